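# Latent-gradient transcriptomics: synthetic counts with an inverse
# mGluR1-vs-mGluR2/3 expression gradient, NNMF on log counts, factor
# selection by marker correlation, and gene/cell ordering by the latent
# factor.

#' Synthetic expression-gradient specification
#'
#' Counts are Poisson with log-mean \code{b_g + w_g f_c}: \code{f_c} a latent
#' per-cell gradient position (Uniform(0,1)), \code{b_g} a per-gene baseline
#' log-mean, and \code{w_g} a signed loading — positive for group-1 mGluR
#' pathway genes (mGluR1/PLC/DGK/TRPC3 side), negative for group-2
#' (mGluR2/3 side), zero for ionotropic and null genes (uniform AMPAR
#' expression).
#'
#' @param n_genes total genes.
#' @param n_group1,n_group2,n_ionotropic counts of tagged genes; the rest
#'   are null.
#' @param w loading magnitude for group-1 (+w) and group-2 (-w) genes.
#' @param b_range Uniform range of per-gene baseline log-means.
#' @param n_cells number of cells.
#' @return list of class \code{gradient_spec}.
#' @export
gradient_spec <- function(n_genes = 1000, n_group1 = 25, n_group2 = 25,
                          n_ionotropic = 20, w = 2,
                          b_range = c(log(0.5), log(3)), n_cells = 500) {
  stopifnot(n_group1 + n_group2 + n_ionotropic <= n_genes,
            n_cells >= 2, w >= 0)
  structure(as.list(environment()), class = "gradient_spec")
}

#' Generate a synthetic gene x cell count matrix
#'
#' @param spec a \code{\link{gradient_spec}}.
#' @param seed integer seed.
#' @return list of class \code{expression_matrix}: \code{counts} (genes x
#'   cells, integer), \code{genes} (data.frame: \code{gene_id},
#'   \code{pathway} in group1_mGluR/group2_mGluR/ionotropic/null,
#'   \code{loading}), \code{cells} (data.frame: \code{cell_id},
#'   \code{f} — the latent gradient, kept as ground truth for recovery
#'   tests).
#' @export
generate_expression <- function(spec = gradient_spec(), seed = 1) {
  if (!is.null(seed)) set.seed(seed)
  pathway <- rep("null", spec$n_genes)
  pathway[seq_len(spec$n_group1)] <- "group1_mGluR"
  pathway[spec$n_group1 + seq_len(spec$n_group2)] <- "group2_mGluR"
  pathway[spec$n_group1 + spec$n_group2 + seq_len(spec$n_ionotropic)] <-
    "ionotropic"
  w_g <- ifelse(pathway == "group1_mGluR", spec$w,
                ifelse(pathway == "group2_mGluR", -spec$w, 0))
  b_g <- stats::runif(spec$n_genes, spec$b_range[1], spec$b_range[2])
  f_c <- stats::runif(spec$n_cells)
  log_mean <- outer(b_g, rep(1, spec$n_cells)) + outer(w_g, f_c)
  if (max(log_mean) > 30) stop("exp overflow: |b + w| too large")
  counts <- matrix(stats::rpois(length(log_mean), exp(log_mean)),
                   nrow = spec$n_genes)
  rownames(counts) <- sprintf("g%04d", seq_len(spec$n_genes))
  colnames(counts) <- sprintf("c%04d", seq_len(spec$n_cells))
  structure(list(counts = counts,
                 genes = data.frame(gene_id = rownames(counts),
                                    pathway = pathway, loading = w_g,
                                    stringsAsFactors = FALSE),
                 cells = data.frame(cell_id = colnames(counts), f = f_c,
                                    stringsAsFactors = FALSE)),
            class = "expression_matrix")
}

#' log(1 + count) transform
#'
#' Keeps the matrix finite and non-negative for NNMF (zero counts map to
#' zero).
#' @param counts non-negative count matrix.
#' @return transformed matrix.
#' @export
log_transform <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  log1p(counts)
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius reconstruction error ||V - WH||_F with the
#' classical multiplicative update rules, which keep W and H entrywise
#' non-negative and never increase the objective. Stops when the relative
#' improvement falls below \code{tol} or after \code{max_iter} iterations.
#'
#' @param v non-negative matrix (genes x cells).
#' @param rank factorization rank.
#' @param seed seed for the random non-negative initialization.
#' @param tol relative-improvement stopping tolerance.
#' @param max_iter iteration cap.
#' @return object of class \code{nnmf_fit}: \code{W} (genes x rank),
#'   \code{H} (rank x cells), \code{error} (final relative Frobenius
#'   error), \code{error_trace}, \code{iterations}, \code{converged}.
#' @export
nnmf <- function(v, rank = 3, seed = 1, tol = 1e-6, max_iter = 500) {
  if (any(v < 0)) stop("matrix must be non-negative")
  if (all(v == 0)) stop("matrix is all zero")
  stopifnot(rank >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(v); m <- ncol(v)
  W <- matrix(stats::runif(n * rank, 0.1, 1), n, rank)
  H <- matrix(stats::runif(rank * m, 0.1, 1), rank, m)
  eps <- .Machine$double.eps
  v_norm <- sqrt(sum(v^2))
  err <- numeric(0)
  prev <- Inf
  met_tol <- FALSE
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, v)) / (crossprod(W) %*% H + eps)
    W <- W * (v %*% t(H)) / (W %*% tcrossprod(H) + eps)
    e <- sqrt(sum((v - W %*% H)^2)) / v_norm
    err <- c(err, e)
    if (is.finite(prev) && (prev - e) < tol * max(prev, eps)) {
      prev <- e
      met_tol <- TRUE
      break
    }
    prev <- e
  }
  structure(list(W = W, H = H, rank = rank, error = prev,
                 error_trace = err, iterations = length(err),
                 converged = met_tol),
            class = "nnmf_fit")
}

#' @export
print.nnmf_fit <- function(x, ...) {
  cat(sprintf(paste0("NNMF: rank %d, %d iterations, relative Frobenius ",
                     "error %.4g%s\n"),
              x$rank, x$iterations, x$error,
              if (!x$converged) " [iteration cap reached]" else ""))
  invisible(x)
}

#' Select the gradient-carrying factor
#'
#' Returns the factor whose cell loadings (row of H) correlate most strongly
#' in absolute Pearson r with the mean log-expression of a positive marker
#' gene set. The loadings of the selected factor are canonicalized so the
#' marker correlation is positive.
#'
#' @param model an \code{\link{nnmf}} fit.
#' @param log_mat the log-transformed matrix the model was fitted to (with
#'   gene rownames).
#' @param markers character vector of positive marker gene ids.
#' @param warn_below warn when the best |r| is below this value.
#' @return list: \code{factor} (index), \code{r} (signed marker
#'   correlation), \code{loadings} (canonicalized cell loadings).
#' @export
select_gradient_factor <- function(model, log_mat, markers,
                                   warn_below = 0.3) {
  idx <- match(markers, rownames(log_mat))
  if (any(is.na(idx))) stop("markers absent from matrix: ",
                            paste(markers[is.na(idx)], collapse = ", "))
  marker_mean <- colMeans(log_mat[idx, , drop = FALSE])
  rs <- apply(model$H, 1, function(h)
    if (stats::sd(h) == 0) 0 else stats::cor(h, marker_mean))
  k <- which.max(abs(rs))
  if (abs(rs[k]) < warn_below)
    warning(sprintf("weak marker correlation (max |r| = %.2f)", abs(rs[k])))
  loadings <- model$H[k, ] * sign(rs[k])
  list(factor = k, r = rs[k], loadings = loadings)
}

#' Order cells and correlate genes with the latent factor
#'
#' Cells are sorted by decreasing factor loading; each gene's log-normalized
#' expression is correlated (Pearson) with the loadings; genes are sorted by
#' r and the top \code{top_percent} by |r| are flagged as most
#' differentially expressed along the gradient. Zero-variance genes are
#' excluded (ids reported via the \code{excluded} attribute).
#'
#' @param log_mat log-transformed expression (genes x cells, rownames).
#' @param loadings per-cell factor loadings.
#' @param top_percent flagged fraction (default 0.01 = top 1\%).
#' @param normalize per-gene normalization of the returned ordered matrix:
#'   \code{"max"} (each gene scaled to max 1) or \code{"none"}.
#' @return list of class \code{gene_correlation}: \code{genes} (data.frame
#'   \code{gene_id}, \code{r}, \code{rank}, \code{top_flag}, sorted by r),
#'   \code{cell_order}, \code{matrix} (genes x cells, ordered, normalized).
#' @export
order_and_correlate <- function(log_mat, loadings, top_percent = 0.01,
                                normalize = c("max", "none")) {
  stopifnot(length(loadings) == ncol(log_mat))
  normalize <- match.arg(normalize)
  cell_order <- order(loadings, decreasing = TRUE)
  sds <- apply(log_mat, 1, stats::sd)
  excluded <- rownames(log_mat)[sds == 0]
  keep <- sds > 0
  r <- as.vector(stats::cor(t(log_mat[keep, , drop = FALSE]), loadings))
  genes <- data.frame(gene_id = rownames(log_mat)[keep], r = r,
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$r), ]
  genes$rank <- seq_len(nrow(genes))
  n_top <- ceiling(top_percent * nrow(genes))
  top_ids <- genes$gene_id[order(-abs(genes$r))][seq_len(n_top)]
  genes$top_flag <- genes$gene_id %in% top_ids
  m <- log_mat[genes$gene_id, cell_order, drop = FALSE]
  if (normalize == "max") {
    mx <- apply(m, 1, max)
    m <- m / pmax(mx, .Machine$double.eps)
  }
  structure(list(genes = genes, cell_order = cell_order, matrix = m),
            class = "gene_correlation", excluded = excluded)
}
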