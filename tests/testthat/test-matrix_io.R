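test_that("wide-format round trip preserves entries, strain and condition order", {
  tns <- random_tensor(n = 6, k = 3, p = 0.3, seed = 11)
  for (delim in c("\t", ",")) {
    dir <- withr::local_tempdir()
    paths <- write_tensor(tns, dir = dir, format = "wide", delim = delim)
    back <- read_tensor(paths, format = "wide")
    expect_identical(back$entries, tns$entries)
    expect_identical(back$strains, tns$strains)
    expect_identical(back$conditions, tns$conditions)
  }
})

test_that("long-format round trip preserves entries given declared strains/conditions", {
  tns <- random_tensor(n = 6, k = 2, p = 0.3, seed = 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tensor(tns, path = path, format = "long")
  expect_message(
    back <- read_tensor(path, format = "long", strains = tns$strains,
                        conditions = tns$conditions),
    "treated as 0")
  expect_identical(back$entries, tns$entries)
})

test_that("a single long row over a declared strain universe yields one entry", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("producer\treceiver\tcondition\tvalue\nA\tB\tmedium1\t1", path)
  suppressMessages(
    tns <- read_tensor(path, format = "long", strains = c("A", "B", "C")))
  expect_equal(sum(tns$entries), 1L)
  expect_equal(tns$entries["A", "B", "medium1"], 1L)
  expect_equal(dim(tns$entries), c(3L, 3L, 1L))
})

test_that("validation rejects malformed input with informative errors", {
  # non-binary cell names the offending labels
  dir <- withr::local_tempdir()
  m <- matrix(0L, 3, 3, dimnames = list(c("A","B","C"), c("A","B","C")))
  m["B", "C"] <- 2L
  p <- file.path(dir, "cond1.tsv")
  utils::write.table(data.frame(strain = rownames(m), m), p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_tensor(c(cond1 = p), format = "wide"),
               "non-binary.*2.*'B'.*'C'")
  # nonzero diagonal is a loud error, not silently dropped
  a <- array(0L, c(2, 2, 1), dimnames = list(c("A","B"), c("A","B"), "c1"))
  a["A", "A", 1] <- 1L
  expect_error(inhibition_tensor(a), "diagonal.*'A'")
  # mismatched strain sets name the symmetric difference
  tns <- random_tensor(n = 4, k = 2, seed = 5)
  dir2 <- withr::local_tempdir()
  paths <- write_tensor(tns, dir = dir2, format = "wide")
  sub <- tns$entries[c(1, 2, 3), c(1, 2, 3), 2]
  rownames(sub)[3] <- colnames(sub)[3] <- "zz"
  utils::write.table(data.frame(strain = rownames(sub), sub, check.names = FALSE),
                     paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_tensor(paths, format = "wide"), "symmetric difference")
  # conflicting duplicate long rows
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("producer\treceiver\tcondition\tvalue",
               "A\tB\tc1\t1", "A\tB\tc1\t0"), p2)
  expect_error(suppressMessages(read_tensor(p2, format = "long")),
               "conflicting duplicate")
  expect_error(read_tensor("no/such/file.tsv", format = "wide"),
               "no/such/file.tsv")
})

test_that("union network has one edge per detected ordered pair with exact support", {
  a <- array(0L, c(3, 3, 3), dimnames = list(c("A","B","C"), c("A","B","C"),
                                             c("c1","c2","c3")))
  a["A", "B", c(1, 2, 3)] <- 1L   # detected everywhere
  a["B", "C", 2] <- 1L            # one condition only
  net <- union_network(inhibition_tensor(a))
  expect_equal(nrow(net$edges), 2L)
  ab <- net$edges[net$edges$producer == "A", ]
  expect_equal(ab$support[[1]], c("c1", "c2", "c3"))
  expect_equal(ab$support_count, 3L)
  bc <- net$edges[net$edges$producer == "B", ]
  expect_equal(bc$support[[1]], "c2")
  # all-zero tensor -> empty network
  z <- union_network(inhibition_tensor(array(0L, c(3, 3, 2)),
                                       strains = c("A","B","C")))
  expect_equal(nrow(z$edges), 0L)
})

test_that("condition slices partition the detections and bound the union", {
  tns <- random_tensor(n = 7, k = 3, p = 0.25, seed = 21)
  net <- union_network(tns)
  slices <- lapply(tns$conditions, condition_slice, tensor = tns)
  total <- sum(vapply(slices, function(s) nrow(s$edges), integer(1)))
  expect_equal(total, sum(tns$entries))            # partition identity
  expect_lte(nrow(net$edges), total)
  expect_equal(total - nrow(net$edges),
               sum(net$edges$support_count - 1L))  # equality iff no support >= 2
  expect_error(condition_slice(tns, "nope"), "unknown condition")
  # a condition with zero detections gives an empty slice
  tns$entries[, , 2] <- 0L
  tns2 <- inhibition_tensor(tns$entries, tns$strains, tns$conditions)
  expect_equal(nrow(condition_slice(tns2, tns$conditions[2])$edges), 0L)
})

test_that("union_network is idempotent through long-format re-serialization", {
  tns <- random_tensor(n = 6, k = 3, p = 0.3, seed = 31)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tensor(tns, path = path, format = "long")
  suppressMessages(
    back <- read_tensor(path, format = "long", strains = tns$strains,
                        conditions = tns$conditions))
  n1 <- union_network(tns); n2 <- union_network(back)
  expect_identical(n1$edges, n2$edges)
})

test_that("strain metadata attaches phylum labels and must cover all strains", {
  tns <- random_tensor(n = 4, k = 2, seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_tensor(tns, dir = dir, format = "wide")
  meta <- data.frame(strain = tns$strains,
                     phylum = rep(c("Firmicutes", "Proteobacteria"), 2))
  withmeta <- read_tensor(paths, format = "wide", metadata = meta)
  expect_identical(unname(withmeta$phylum[tns$strains[2]]), "Proteobacteria")
  expect_error(
    read_tensor(paths, format = "wide", metadata = meta[-1, ]),
    "phylum labels missing")
})
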