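# Relative gene expression transformations.
#
# Raw expression T (genes x conditions, non-negative, any platform units) is
# mapped row-wise into [0, 1] by one of three reference schemes before it is
# matched against flux variability-scaled fluxes. A small constant omega
# guards every denominator; rows whose guard fails get a scheme-neutral
# constant so no gene has to be dropped.

#' Read a gene-by-condition expression table
#'
#' Expects a TSV/CSV with a header row of condition ids and gene ids in the
#' first column. Values must be non-negative.
#'
#' @param path File path.
#' @param sep Field separator; guessed from the extension when `NULL`.
#' @return Numeric matrix with gene rownames and condition colnames.
#' @export
read_expression <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- as.character(df[[1]])
  storage.mode(mat) <- "double"
  if (any(mat < 0, na.rm = TRUE)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  mat
}

#' Transform raw expression into relative expression in \[0, 1\]
#'
#' Three row-wise schemes are available:
#' * `max_reference`: divide by the row maximum; the condition with the
#'   highest expression maps to 1.
#' * `minmax`: min-max scaling; row minimum maps to 0, row maximum to 1.
#' * `mean_reference`: the row mean maps to 0.5; values above the mean are
#'   min-max scaled between mean and max into (0.5, 1\], values below between
#'   min and mean into \[0, 0.5).
#'
#' For `mean_reference` the lower branch defaults to the monotone form
#' `(T - min) / (2 (mean - min))`, so the transform is non-decreasing within a
#' row and the row minimum maps to 0. `mean_low = "as_printed"` instead uses
#' the reflected form `(mean - T) / (2 (mean - min))`, which maps the row
#' minimum to 0.5 and is non-monotone; it is provided for comparison only.
#'
#' Degenerate rows (range, upper range or lower range not exceeding `omega`)
#' get the neutral constant 0.5 (`minmax`, `mean_reference`) or 1
#' (`max_reference`, when the row maximum is positive); all-zero rows get 0.5
#' under every scheme.
#'
#' @param T Non-negative numeric matrix, genes x conditions (needs rownames
#'   and colnames for downstream alignment).
#' @param scheme One of `"mean_reference"`, `"max_reference"`, `"minmax"`.
#' @param omega Small positive denominator guard (default 0.001).
#' @param mean_low Lower-branch form for `mean_reference`: `"monotone"`
#'   (default) or `"as_printed"`.
#' @return A `relative_expression` object: the transformed matrix plus
#'   attributes `scheme` and `omega`.
#' @examples
#' T <- matrix(c(2, 4, 6), 1, dimnames = list("g1", c("c1", "c2", "c3")))
#' relative_expression(T, "mean_reference")   # 0, 0.5, 1
#' @export
relative_expression <- function(T,
                                scheme = c("mean_reference", "max_reference",
                                           "minmax"),
                                omega = 0.001,
                                mean_low = c("monotone", "as_printed")) {
  scheme <- match.arg(scheme)
  mean_low <- match.arg(mean_low)
  T <- as.matrix(T)
  if (any(T < 0, na.rm = TRUE)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  if (scheme != "max_reference" && ncol(T) < 2) {
    stop(scheme, " needs at least two conditions", call. = FALSE)
  }
  stopifnot(omega > 0)
  rmax <- apply(T, 1, max)
  rmin <- apply(T, 1, min)
  rmean <- rowMeans(T)
  g <- matrix(0.5, nrow(T), ncol(T), dimnames = dimnames(T))
  if (scheme == "max_reference") {
    ok <- rmax > 0
    g[ok, ] <- T[ok, , drop = FALSE] / rmax[ok]
  } else if (scheme == "minmax") {
    ok <- (rmax - rmin) > omega
    g[ok, ] <- (T[ok, , drop = FALSE] - rmin[ok]) / (rmax[ok] - rmin[ok])
  } else {
    for (i in seq_len(nrow(T))) {
      hi_ok <- (rmax[i] - rmean[i]) > omega
      lo_ok <- (rmean[i] - rmin[i]) > omega
      for (j in seq_len(ncol(T))) {
        if (T[i, j] >= rmean[i]) {
          g[i, j] <- if (hi_ok) {
            (T[i, j] - rmean[i]) / (2 * (rmax[i] - rmean[i])) + 0.5
          } else 0.5
        } else {
          g[i, j] <- if (!lo_ok) 0.5
          else if (mean_low == "monotone") {
            (T[i, j] - rmin[i]) / (2 * (rmean[i] - rmin[i]))
          } else {
            (rmean[i] - T[i, j]) / (2 * (rmean[i] - rmin[i]))
          }
        }
      }
    }
  }
  g <- pmin(pmax(g, 0), 1)
  structure(g, class = c("relative_expression", class(g)),
            scheme = scheme, omega = omega, mean_low = mean_low)
}

#' Align relative expression rows to the model gene list
#'
#' Output rows are exactly the model's genes in model order. Model genes
#' absent from the table are flagged unmeasured (their expression variables
#' are left unconstrained by the integration MILP); table genes absent from
#' the model are dropped with a message; duplicated gene rows are averaged
#' with a warning.
#'
#' @param rel A [relative_expression()] matrix (or any matrix with gene
#'   rownames).
#' @param net A [metabolic_network()] (typically irreversible).
#' @return Matrix with `length(net$gene_ids)` rows and a logical attribute
#'   `measured` marking genes present in the table.
#' @export
align_to_model <- function(rel, net) {
  stopifnot(inherits(net, "metabolic_network"))
  genes <- net$gene_ids
  tbl_genes <- rownames(rel)
  if (is.null(tbl_genes)) stop("expression matrix must have gene rownames",
                               call. = FALSE)
  if (anyDuplicated(tbl_genes)) {
    warning("duplicated gene ids in expression table; averaging duplicates")
    rel <- do.call(rbind, lapply(split(seq_along(tbl_genes), tbl_genes),
                                 function(ix) colMeans(rel[ix, , drop = FALSE])))
  }
  overlap <- intersect(genes, rownames(rel))
  if (length(overlap) == 0L) {
    stop("no overlap between expression table genes and model genes",
         call. = FALSE)
  }
  dropped <- setdiff(rownames(rel), genes)
  if (length(dropped)) {
    message(length(dropped), " expression row(s) not in the model were dropped")
  }
  out <- matrix(NA_real_, length(genes), ncol(rel),
                dimnames = list(genes, colnames(rel)))
  out[overlap, ] <- rel[overlap, , drop = FALSE]
  attr(out, "measured") <- stats::setNames(genes %in% overlap, genes)
  attr(out, "scheme") <- attr(rel, "scheme")
  out
}

#' Write a relative-expression matrix as TSV
#'
#' Same layout as [read_expression()]: first column gene ids, header row of
#' condition ids.
#'
#' @param rel Matrix with gene rownames.
#' @param path Output path.
#' @export
write_expression <- function(rel, path) {
  df <- data.frame(gene = rownames(rel), as.data.frame(unclass(rel)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
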