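#' Construct an inhibition tensor
#'
#' The central raw-data container: a strains x strains x conditions binary
#' array recording, for each assay condition, whether a producer strain
#' (row) inhibited a receiver strain (column). Entry `[p, r, c] = 1` means
#' producer `p` produced a visible zone of inhibition against receiver `r`
#' on condition (medium) `c`.
#'
#' @param entries numeric/integer array of dimension `S x S x K` (or an
#'   `S x S` matrix for a single condition) with 0/1 entries and zero
#'   diagonal in every condition slice.
#' @param strains character vector of strain identifiers; defaults to the
#'   array's row dimnames.
#' @param conditions character vector of condition (medium) names; defaults
#'   to the array's third-dimension dimnames.
#' @param phylum optional named character vector mapping every strain to a
#'   phylum label (used only for export/reporting).
#' @return an object of class `inhibition_tensor`: a list with elements
#'   `entries` (integer array with dimnames), `strains`, `conditions`,
#'   `phylum`.
#' @examples
#' a <- array(0L, c(3, 3, 2), dimnames = list(c("A","B","C"), c("A","B","C"),
#'                                            c("m1","m2")))
#' a["A", "B", "m1"] <- 1L
#' tns <- inhibition_tensor(a)
#' @export
inhibition_tensor <- function(entries, strains = NULL, conditions = NULL,
                              phylum = NULL) {
  if (is.matrix(entries)) {
    entries <- array(entries, dim = c(dim(entries), 1L),
                     dimnames = c(dimnames(entries), list(NULL)))
  }
  if (!is.array(entries) || length(dim(entries)) != 3L)
    stop("`entries` must be an S x S x K array or an S x S matrix")
  d <- dim(entries)
  if (d[1] != d[2])
    stop("`entries` must be square in its first two dimensions (got ",
         d[1], " x ", d[2], ")")
  if (is.null(strains)) strains <- dimnames(entries)[[1]]
  if (is.null(strains))
    stop("strain identifiers missing: supply `strains` or row dimnames")
  strains <- as.character(strains)
  if (length(strains) != d[1])
    stop("length(strains) does not match matrix dimension")
  if (anyDuplicated(strains) || any(!nzchar(strains)))
    stop("strain identifiers must be unique and non-empty")
  if (is.null(conditions)) conditions <- dimnames(entries)[[3]]
  if (is.null(conditions)) conditions <- paste0("condition", seq_len(d[3]))
  conditions <- as.character(conditions)
  if (length(conditions) != d[3] || anyDuplicated(conditions))
    stop("condition names must be unique and match the third dimension")

  storage.mode(entries) <- "integer"
  bad <- which(!(entries %in% c(0L, 1L)))
  if (length(bad)) {
    idx <- arrayInd(bad[1], d)
    stop(sprintf(
      "non-binary entry %s at producer '%s', receiver '%s', condition '%s'",
      entries[bad[1]], strains[idx[1]], strains[idx[2]], conditions[idx[3]]))
  }
  for (k in seq_len(d[3])) {
    dg <- diag(entries[, , k])
    if (any(dg != 0L))
      stop(sprintf(
        "nonzero diagonal (self-inhibition) for strain '%s' in condition '%s'",
        strains[which(dg != 0L)[1]], conditions[k]))
  }
  if (!is.null(phylum)) {
    phylum <- vapply(phylum, as.character, character(1))
    missing_ph <- setdiff(strains, names(phylum))
    if (length(missing_ph))
      stop("phylum labels missing for strains: ",
           paste(missing_ph, collapse = ", "))
    phylum <- phylum[strains]
  }
  dimnames(entries) <- list(strains, strains, conditions)
  structure(list(entries = entries, strains = strains,
                 conditions = conditions, phylum = phylum),
            class = "inhibition_tensor")
}

#' @export
print.inhibition_tensor <- function(x, ...) {
  cat("Inhibition tensor:", length(x$strains), "strains x",
      length(x$conditions), "conditions\n")
  det <- vapply(x$conditions, function(k) sum(x$entries[, , k]), integer(1))
  cat("Detections per condition:\n")
  print(det)
  invisible(x)
}

n_strains <- function(tensor) length(tensor$strains)

infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a multi-condition inhibition tensor from delimited files
#'
#' Two serializations are supported. `wide`: one square table per condition,
#' first column and header row both strain IDs, rows = producers, columns =
#' receivers. `long`: sparse edge table(s) with columns
#' `producer receiver condition value`; rows not listed are taken as 0
#' (absence of inhibition), reported once as a message with a count.
#'
#' @param paths for `wide`, a named character vector/list mapping condition
#'   name to file path (names default to file basenames); for `long`, one or
#'   more paths whose rows carry their own condition column.
#' @param format `"wide"` or `"long"`.
#' @param strains optional character vector declaring the strain universe
#'   (required to represent strains with no detections in `long` files when
#'   they never appear). For `wide`, the canonical strain order is taken from
#'   the first file and enforced on the rest.
#' @param conditions optional condition order for `long` input; defaults to
#'   order of first appearance.
#' @param delim field delimiter; by default inferred from the extension
#'   (`.csv` comma, otherwise tab).
#' @param metadata optional path to a two-column `strain phylum` table, or a
#'   data.frame with those columns.
#' @return an [inhibition_tensor()]
#' @export
read_tensor <- function(paths, format = c("wide", "long"), strains = NULL,
                        conditions = NULL, delim = NULL, metadata = NULL) {
  format <- match.arg(format)
  paths <- unlist(paths)
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files))
    stop("input file not found: ", paste(missing_files, collapse = ", "))
  tns <- if (format == "wide") {
    read_tensor_wide(paths, delim)
  } else {
    read_tensor_long(paths, strains, conditions, delim)
  }
  if (!is.null(metadata)) {
    meta <- if (is.data.frame(metadata)) metadata else
      utils::read.delim(metadata, sep = infer_delim(metadata, delim),
                        stringsAsFactors = FALSE)
    if (!all(c("strain", "phylum") %in% names(meta)))
      stop("metadata table must have columns `strain` and `phylum`")
    ph <- stats::setNames(as.character(meta$phylum), meta$strain)
    tns <- inhibition_tensor(tns$entries, tns$strains, tns$conditions,
                             phylum = ph)
  }
  tns
}

read_tensor_wide <- function(paths, delim = NULL) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  mats <- lapply(seq_along(paths), function(i) {
    p <- paths[i]
    df <- utils::read.delim(p, sep = infer_delim(p, delim), row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df)
    if (nrow(m) != ncol(m))
      stop("file '", p, "' is not square: ", nrow(m), " rows x ",
           ncol(m), " columns")
    if (!identical(rownames(m), colnames(m)))
      stop("file '", p, "' has mismatched row/column strain ordering")
    m
  })
  canonical <- rownames(mats[[1]])
  for (i in seq_along(mats)[-1]) {
    have <- rownames(mats[[i]])
    if (!setequal(have, canonical)) {
      sdiff <- c(setdiff(canonical, have), setdiff(have, canonical))
      stop("strain sets differ between '", paths[1], "' and '", paths[i],
           "'; symmetric difference: ", paste(sdiff, collapse = ", "))
    }
    mats[[i]] <- mats[[i]][canonical, canonical]  # enforce canonical order
  }
  entries <- array(0L, dim = c(length(canonical), length(canonical),
                               length(mats)),
                   dimnames = list(canonical, canonical, names(paths)))
  for (i in seq_along(mats)) {
    m <- mats[[i]]
    bad <- which(!(m %in% c(0, 1)))
    if (length(bad)) {
      idx <- arrayInd(bad[1], dim(m))
      stop(sprintf(
        "non-binary entry %s in '%s' at row '%s', column '%s'",
        m[bad[1]], paths[i], canonical[idx[1]], canonical[idx[2]]))
    }
    entries[, , i] <- as.integer(m)
  }
  inhibition_tensor(entries, canonical, names(paths))
}

read_tensor_long <- function(paths, strains = NULL, conditions = NULL,
                             delim = NULL) {
  rows <- do.call(rbind, lapply(paths, function(p) {
    df <- utils::read.delim(p, sep = infer_delim(p, delim),
                            stringsAsFactors = FALSE)
    need <- c("producer", "receiver", "condition", "value")
    if (!all(need %in% names(df)))
      stop("long-format file '", p, "' must have columns: ",
           paste(need, collapse = ", "))
    df[need]
  }))
  if (!all(rows$value %in% c(0, 1))) {
    i <- which(!(rows$value %in% c(0, 1)))[1]
    stop(sprintf("non-binary entry %s at producer '%s', receiver '%s', condition '%s'",
                 rows$value[i], rows$producer[i], rows$receiver[i],
                 rows$condition[i]))
  }
  key <- paste(rows$producer, rows$receiver, rows$condition, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(rows$value, key, function(v) length(unique(v)))
    conflict <- names(agg)[agg > 1]
    if (length(conflict)) {
      parts <- strsplit(conflict[1], "\r", fixed = TRUE)[[1]]
      stop(sprintf(
        "conflicting duplicate rows for producer '%s', receiver '%s', condition '%s'",
        parts[1], parts[2], parts[3]))
    }
    rows <- rows[!duplicated(key), ]
  }
  seen <- unique(c(rows$producer, rows$receiver))
  if (is.null(strains)) strains <- seen
  extra <- setdiff(seen, strains)
  if (length(extra))
    stop("strains in file but not in declared strain set: ",
         paste(extra, collapse = ", "))
  if (is.null(conditions)) conditions <- unique(rows$condition)
  if (!all(rows$condition %in% conditions))
    stop("conditions in file but not declared: ",
         paste(setdiff(rows$condition, conditions), collapse = ", "))
  entries <- array(0L, dim = c(length(strains), length(strains),
                               length(conditions)),
                   dimnames = list(strains, strains, conditions))
  pos <- rows[rows$value == 1, , drop = FALSE]
  if (nrow(pos)) {
    entries[cbind(match(pos$producer, strains), match(pos$receiver, strains),
                  match(pos$condition, conditions))] <- 1L
  }
  n_missing <- length(strains)^2 * length(conditions) - nrow(rows)
  if (n_missing > 0)
    message(n_missing, " unlisted (producer, receiver, condition) cells treated as 0")
  inhibition_tensor(entries, strains, conditions)
}

#' Write an inhibition tensor to delimited files
#'
#' Inverse of [read_tensor()]. Wide format writes one square table per
#' condition under `dir` (named `<condition>.tsv` or `.csv`); long format
#' writes a single sparse edge table of the positive cells.
#'
#' @param tensor an [inhibition_tensor()]
#' @param dir output directory (wide) -- created if absent.
#' @param path output file (long).
#' @param format `"wide"` or `"long"`.
#' @param delim field delimiter (default tab).
#' @return invisibly, the paths written.
#' @export
write_tensor <- function(tensor, dir = NULL, path = NULL,
                         format = c("wide", "long"), delim = "\t") {
  format <- match.arg(format)
  if (format == "wide") {
    stopifnot(!is.null(dir))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ext <- if (delim == ",") ".csv" else ".tsv"
    out <- vapply(tensor$conditions, function(k) {
      p <- file.path(dir, paste0(k, ext))
      m <- tensor$entries[, , k]
      utils::write.table(
        data.frame(strain = rownames(m), m, check.names = FALSE),
        p, sep = delim, quote = FALSE, row.names = FALSE)
      p
    }, character(1))
    return(invisible(out))
  }
  stopifnot(!is.null(path))
  idx <- which(tensor$entries == 1L, arr.ind = TRUE)
  df <- data.frame(
    producer = tensor$strains[idx[, 1]],
    receiver = tensor$strains[idx[, 2]],
    condition = tensor$conditions[idx[, 3]],
    value = 1L)
  df <- df[order(match(df$condition, tensor$conditions),
                 match(df$producer, tensor$strains),
                 match(df$receiver, tensor$strains)), ]
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}
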