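#' Stage-wise expression matrix
#'
#' Container for a protein/gene abundance matrix measured in replicates of
#' ordered phenotypic stages (e.g. monolayer, moruloid, blastuloid).
#'
#' @param values numeric matrix, entities x samples; non-negative, `NA`
#'   marks missing abundances. Row names are entity ids.
#' @param stages character vector (one per column) naming each sample's stage;
#'   stage order of first appearance is preserved.
#' @return object of class `stage_expression`.
#' @export
stage_expression <- function(values, stages) {
  values <- as.matrix(values)
  stopifnot(!is.null(rownames(values)), ncol(values) == length(stages))
  if (any(values < 0, na.rm = TRUE)) stop("negative abundance values")
  if (any(!is.finite(values) & !is.na(values))) stop("non-finite abundance values")
  stages <- as.character(stages)
  structure(list(values = values, stages = stages,
                 stage_levels = unique(stages)),
            class = "stage_expression")
}

#' @export
print.stage_expression <- function(x, ...) {
  cat("<stage_expression> ", nrow(x$values), " entities, ",
      length(x$stage_levels), " stages (",
      paste(x$stage_levels, collapse = ", "), "), ",
      ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

stage_columns <- function(m, stage) which(m$stages == stage)

#' Presence filter on a stage expression matrix
#'
#' First removes entities missing in every sample, then keeps an entity iff
#' it is observed in at least 50% of the replicates of at least one stage.
#'
#' @param m a [stage_expression()].
#' @return the filtered [stage_expression()]; may have zero rows (logged).
#' @export
filter_proteins <- function(m) {
  v <- m$values
  v <- v[rowSums(!is.na(v)) > 0, , drop = FALSE]
  keep <- vapply(seq_len(nrow(v)), function(i) {
    any(vapply(m$stage_levels, function(s) {
      cols <- stage_columns(m, s)
      mean(!is.na(v[i, cols])) >= 0.5
    }, logical(1)))
  }, logical(1))
  if (!any(keep)) message("filter_proteins: no entity passed the 50% rule")
  stage_expression(v[keep, , drop = FALSE], m$stages)
}

#' Impute missing abundances
#'
#' Stage-wise rule: if an entity is observed in at least 50% of a stage's
#' replicates, its missing cells in that stage become the mean of the stage's
#' observed replicates. Otherwise the stage's cells are replaced by the
#' global minimum of the (filtered) matrix. Whether an observed singleton in
#' a failing stage is also overwritten is controlled by `replace_observed`
#' (default `TRUE`: the whole stage-row is set to the global minimum).
#'
#' @param m a filtered [stage_expression()].
#' @param replace_observed overwrite observed values in stages failing the
#'   50% rule?
#' @return a [stage_expression()] with no missing values.
#' @export
impute_expression <- function(m, replace_observed = TRUE) {
  v <- m$values
  gmin <- suppressWarnings(min(v, na.rm = TRUE))
  if (!is.finite(gmin)) stop("matrix has no observed value to impute from")
  for (s in m$stage_levels) {
    cols <- stage_columns(m, s)
    for (i in seq_len(nrow(v))) {
      obs <- !is.na(v[i, cols])
      if (all(obs)) next
      if (mean(obs) >= 0.5) {
        v[i, cols[!obs]] <- mean(v[i, cols[obs]])
      } else if (replace_observed) {
        v[i, cols] <- gmin
      } else {
        v[i, cols[!obs]] <- gmin
      }
    }
  }
  stage_expression(v, m$stages)
}

#' Merge replicates and log-normalize
#'
#' Replicates of each stage are merged by their arithmetic mean, then the
#' merged values are log-transformed (base 10 by default, matching the
#' normalization applied before model extraction).
#'
#' @param m an imputed [stage_expression()] (no missing values).
#' @param log_base base of the log transform; `NA` skips the transform.
#' @return numeric matrix, entities x stages.
#' @export
collapse_and_normalize <- function(m, log_base = 10) {
  if (anyNA(m$values)) stop("merge requires an imputed matrix (no NA)")
  out <- vapply(m$stage_levels, function(s)
    rowMeans(m$values[, stage_columns(m, s), drop = FALSE]),
    numeric(nrow(m$values)))
  out <- matrix(out, nrow = nrow(m$values),
                dimnames = list(rownames(m$values), m$stage_levels))
  if (!is.na(log_base)) {
    if (any(out <= 0)) stop("non-positive merged value; cannot log-transform")
    out <- log(out, base = log_base)
  }
  out
}

#' Differential expression between two stages
#'
#' Per entity: log2 fold-change of mean abundance (B vs A) and a Welch
#' two-sample t-test p value, flagged up/down at `|log2FC| >= lfc_cutoff`
#' and `p < p_cutoff`. If both groups have zero variance, p is 1 when the
#' means agree and 0 otherwise.
#'
#' @param a,b numeric matrices of replicate abundances (entities x replicates)
#'   with matching row names, stage A (initial) and stage B (later).
#' @param lfc_cutoff absolute log2 fold-change threshold (default 1).
#' @param p_cutoff p-value threshold (default 0.05).
#' @param adjust multiplicity adjustment passed to [stats::p.adjust()]
#'   (default `"none"`, i.e. raw p values; `"BH"` available).
#' @return data.frame with `entity`, `log2fc`, `p`, `p_adj`, `direction`.
#' @export
differential_expression <- function(a, b, lfc_cutoff = 1, p_cutoff = 0.05,
                                    adjust = "none") {
  stopifnot(identical(rownames(a), rownames(b)))
  n <- nrow(a)
  lfc <- p <- numeric(n)
  for (i in seq_len(n)) {
    xa <- a[i, ]; xb <- b[i, ]
    ma <- mean(xa); mb <- mean(xb)
    lfc[i] <- log2(mb / ma)
    p[i] <- tryCatch(stats::t.test(xb, xa, var.equal = FALSE)$p.value,
                     error = function(e)
                       if (isTRUE(all.equal(ma, mb))) 1 else 0)
  }
  p_adj <- stats::p.adjust(p, method = adjust)
  direction <- ifelse(abs(lfc) >= lfc_cutoff & p_adj < p_cutoff,
                      ifelse(lfc > 0, "up", "down"), "ns")
  data.frame(entity = rownames(a), log2fc = lfc, p = p, p_adj = p_adj,
             direction = direction, stringsAsFactors = FALSE)
}

#' Write / read a stage expression matrix as TSV
#'
#' The on-disk format has a two-level header: the first line gives the stage
#' of each sample column, the second the replicate label; rows are entities.
#'
#' @param m a [stage_expression()].
#' @param path TSV file.
#' @return `path` (write) or a [stage_expression()] (read).
#' @export
write_stage_expression <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("stage", m$stages), collapse = "\t"), con)
  writeLines(paste(c("id", colnames(m$values) %||%
                       paste0("s", seq_len(ncol(m$values)))), collapse = "\t"), con)
  utils::write.table(m$values, con, sep = "\t", col.names = FALSE,
                     row.names = TRUE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_stage_expression
#' @param path TSV file produced by [write_stage_expression()].
#' @export
read_stage_expression <- function(path) {
  lines <- readLines(path)
  stages <- strsplit(lines[1], "\t")[[1]][-1]
  reps <- strsplit(lines[2], "\t")[[1]][-1]
  body <- utils::read.delim(text = lines[-(1:2)], header = FALSE,
                            stringsAsFactors = FALSE, na.strings = "")
  vals <- as.matrix(body[, -1, drop = FALSE])
  mode(vals) <- "numeric"
  dimnames(vals) <- list(body[[1]], reps)
  stage_expression(vals, stages)
}
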