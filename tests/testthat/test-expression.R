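# Relative-expression transformations and model alignment.

row_mat <- function(...) {
  v <- c(...)
  matrix(v, 1, dimnames = list("g1", paste0("c", seq_along(v))))
}

test_that("max-reference divides by the row maximum", {
  expect_equal(as.numeric(relative_expression(row_mat(2, 4, 8), "max_reference")),
               c(0.25, 0.5, 1.0))
  expect_equal(as.numeric(relative_expression(row_mat(5, 5, 5), "max_reference")),
               c(1, 1, 1))
  expect_equal(as.numeric(relative_expression(row_mat(0, 0, 0), "max_reference")),
               c(0.5, 0.5, 0.5))
})

test_that("min-max scaling maps row extremes to 0 and 1, guards tiny ranges", {
  expect_equal(as.numeric(relative_expression(row_mat(2, 4, 8), "minmax")),
               c(0, 1 / 3, 1))
  # range below the omega guard falls back to the neutral constant
  expect_equal(as.numeric(relative_expression(row_mat(5, 5.0005), "minmax")),
               c(0.5, 0.5))
  # just above the guard it scales
  out <- as.numeric(relative_expression(row_mat(5, 5.002), "minmax"))
  expect_equal(out, c(0, 1))
})

test_that("mean-reference anchors mean at 0.5, max at 1, min at 0", {
  out <- as.numeric(relative_expression(row_mat(2, 4, 6), "mean_reference"))
  expect_equal(out[2], 0.5)   # value at the row mean
  expect_equal(out[3], 1.0)   # value at the row maximum
  expect_equal(out[1], 0.0)   # monotone lower branch: row minimum -> 0

  # the as-printed lower branch is the reflection: minimum maps to 0.5
  out2 <- as.numeric(relative_expression(row_mat(2, 4, 6), "mean_reference",
                                         mean_low = "as_printed"))
  expect_equal(out2[1], 0.5)
  expect_equal(out2[2:3], c(0.5, 1.0))
})

test_that("all three schemes map arbitrary non-negative rows into [0,1]", {
  set.seed(99)
  for (rep in 1:250) {
    D <- sample(2:8, 1)
    row <- switch(sample(3, 1),
                  stats::runif(D, 0, 1000),
                  stats::rpois(D, 3),
                  rep(stats::runif(1, 0, 10), D))   # constant rows included
    m <- matrix(row, 1, dimnames = list("g", paste0("c", 1:D)))
    for (scheme in c("max_reference", "minmax", "mean_reference")) {
      g <- as.numeric(relative_expression(m, scheme))
      expect_true(all(is.finite(g)))
      expect_true(all(g >= 0 & g <= 1))
    }
  }
})

test_that("max-reference and minmax are invariant to positive row scaling", {
  set.seed(5)
  m <- matrix(stats::runif(40, 1, 50), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:4)))
  for (scheme in c("max_reference", "minmax")) {
    a <- relative_expression(m, scheme)
    b <- relative_expression(3.7 * m, scheme)
    expect_equal(unclass(a), unclass(b), ignore_attr = TRUE)
  }
})

test_that("mean-reference (monotone form) is non-decreasing within rows", {
  set.seed(13)
  for (rep in 1:50) {
    row <- sort(stats::runif(6, 0, 100))
    m <- matrix(row, 1, dimnames = list("g", paste0("c", 1:6)))
    g <- as.numeric(relative_expression(m, "mean_reference"))
    expect_true(all(diff(g) >= -1e-12))
    gm <- as.numeric(relative_expression(m, "minmax"))
    expect_true(all(diff(gm) >= -1e-12))
  }
})

test_that("negative expression values are rejected", {
  expect_error(relative_expression(row_mat(-1, 2, 3), "minmax"), "non-negative")
})

test_that("alignment restricts to model genes, flags unmeasured, averages duplicates", {
  net <- to_irreversible(make_network("parallel_branches"))
  genes <- net$gene_ids
  T <- matrix(stats::runif(length(genes) * 2, 1, 10), length(genes), 2,
              dimnames = list(genes, c("C1", "C2")))
  rel <- relative_expression(T, "minmax")
  al <- align_to_model(rel, net)
  expect_equal(rownames(al), genes)
  expect_true(all(attr(al, "measured")))

  # one gene missing -> flagged, row NA
  rel2 <- rel[-1, , drop = FALSE]
  al2 <- align_to_model(rel2, net)
  expect_equal(rownames(al2), genes)
  expect_false(attr(al2, "measured")[[genes[1]]])
  expect_true(all(is.na(al2[genes[1], ])))

  # extra genes dropped with a message
  rel3 <- rbind(rel, ghost = c(0.1, 0.9))
  expect_message(al3 <- align_to_model(rel3, net), "dropped")
  expect_equal(rownames(al3), genes)

  # duplicates averaged with a warning
  rel4 <- rbind(rel, rel[1, , drop = FALSE])
  expect_warning(al4 <- align_to_model(rel4, net), "duplicated")
  expect_equal(al4[genes[1], ], colMeans(rel[c(1, 1), ]))

  # zero overlap errors
  rel5 <- matrix(0.5, 2, 2, dimnames = list(c("x1", "x2"), c("C1", "C2")))
  expect_error(align_to_model(rel5, net), "overlap")
})

test_that("expression tables round-trip through TSV", {
  T <- matrix(c(2, 4, 6, 1, 5, 9), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("C1", "C2", "C3")))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_expression(T, tmp)
  back <- read_expression(tmp)
  expect_equal(back, T)
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tC1\tC2", "g1\t-3\t2"), tmp2)
  expect_error(read_expression(tmp2), "non-negative")
})
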