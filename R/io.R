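# Plain-text serialization: CSV spike trains and traces with '#' metadata
# headers; Matrix Market (MTX) counts with TSV gene/cell label files.

.write_header <- function(con, meta) {
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
}

#' Write spike trains to CSV
#'
#' Columns \code{cell_id,trial,spike_time_s} (offset-referenced, 6
#' decimals), preceded by '#'-prefixed metadata lines.
#'
#' @param trains a \code{spike_trains} data.frame (or rbind of several).
#' @param path output file.
#' @param meta named list of metadata (protocol, seed, units, ...).
#' @export
write_spike_csv <- function(trains, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  .write_header(con, c(list(units = "seconds, t = 0 at stimulus offset"),
                       meta))
  writeLines("cell_id,trial,spike_time_s", con)
  if (nrow(trains))
    writeLines(sprintf("%s,%d,%.6f", trains$cell_id, trains$trial,
                       trains$time), con)
  invisible(path)
}

#' Read spike trains from CSV
#'
#' @param path file written by \code{\link{write_spike_csv}}.
#' @return a \code{spike_trains} data.frame; '#' metadata lines are returned
#'   in the \code{meta} attribute.
#' @export
read_spike_csv <- function(path) {
  lines <- readLines(path)
  meta <- sub("^# ", "", lines[startsWith(lines, "#")])
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  names(df)[names(df) == "spike_time_s"] <- "time"
  attr(df, "meta") <- meta
  attr(df, "n_trials") <- if (nrow(df)) max(df$trial) else 0L
  class(df) <- c("spike_trains", "data.frame")
  df
}

#' Write a current or rate trace to CSV (long format)
#'
#' Columns \code{cell_id,time_s,value} plus one column per component for
#' current traces; '#'-prefixed metadata header records units and the sign
#' convention (inward/excitatory currents are positive in these traces;
#' physiologically, inward current is negative in voltage clamp).
#'
#' @param trace a \code{current_trace} or \code{rate_trace}.
#' @param path output file.
#' @param meta named list of extra metadata.
#' @export
write_trace_csv <- function(trace, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(trace, "current_trace")) {
    .write_header(con, c(list(
      units = "pA",
      sign = "inward (excitatory) positive; physiological voltage-clamp sign is inverted"),
      meta))
    writeLines("cell_id,time_s,value,mGluR1,mGluR23,ionotropic", con)
    writeLines(sprintf("%s,%.6f,%.6g,%.6g,%.6g,%.6g", trace$cell_id,
                       trace$time, trace$total, trace$mGluR1, trace$mGluR23,
                       trace$ionotropic), con)
  } else {
    .write_header(con, c(list(units = "Hz"), meta))
    writeLines("cell_id,time_s,value", con)
    writeLines(sprintf("%s,%.6f,%.6g", trace$cell_id, trace$time,
                       trace$rate), con)
  }
  invisible(path)
}

#' Read a trace CSV
#'
#' @param path file written by \code{\link{write_trace_csv}}.
#' @return a \code{current_trace} or \code{rate_trace} depending on the
#'   columns present.
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  meta <- sub("^# ", "", lines[startsWith(lines, "#")])
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  out <- if ("mGluR1" %in% names(df)) {
    structure(list(time = df$time_s, total = df$value, mGluR1 = df$mGluR1,
                   mGluR23 = df$mGluR23, ionotropic = df$ionotropic,
                   cell_id = df$cell_id[1], protocol = NULL),
              class = "current_trace")
  } else {
    structure(list(time = df$time_s, rate = df$value,
                   cell_id = df$cell_id[1], n_trials = NA_integer_,
                   kind = "file"),
              class = "rate_trace")
  }
  attr(out, "meta") <- meta
  out
}

#' Write an expression matrix as MTX + TSV labels
#'
#' Matrix Market coordinate format for the counts, with \code{genes.tsv}
#' (gene_id, pathway, loading) and \code{cells.tsv} (cell_id, and the latent
#' gradient when present) alongside.
#'
#' @param expr an \code{expression_matrix}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_expression_mtx <- function(expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(expr$counts, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  utils::write.table(expr$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(expr$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an expression matrix from MTX + TSV labels
#'
#' @param dir directory written by \code{\link{write_expression_mtx}} (or
#'   any \code{counts.mtx} + \code{genes.tsv} + \code{cells.tsv} triple).
#' @return an \code{expression_matrix}.
#' @export
read_expression_mtx <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  if (nrow(genes) != nrow(counts) || nrow(cells) != ncol(counts))
    stop("label files inconsistent with matrix dimensions")
  rownames(counts) <- genes$gene_id
  colnames(counts) <- cells$cell_id
  structure(list(counts = counts, genes = genes, cells = cells),
            class = "expression_matrix")
}
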