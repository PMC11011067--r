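# qPCR knockdown quantification ----------------------------------------------
#
# Relative expression by the -delta-Ct method: per replicate,
# dCt = Ct_target - Ct_reference (GAPDH); per sample the relative
# expression is 2^-(mean dCt_sample - mean dCt_control), normalised to the
# non-targeting control (NTC), which therefore self-normalises to exactly
# 1. Group differences are assessed on the replicate dCt values by one-way
# ANOVA with Tukey's multiple comparisons.

#' Relative expression from a tidy Ct table
#'
#' @param ct data.frame with columns `sample`, `gene`, `replicate`, `ct`.
#'   Every sample needs the reference gene in each replicate.
#' @param target target gene symbol; defaults to the single non-reference
#'   gene in the table.
#' @param reference reference gene (default `"GAPDH"`).
#' @param control control sample (default `"NTC"`).
#' @param tukey also run one-way ANOVA + Tukey HSD across samples on the
#'   replicate dCt values.
#' @return list with `samples` (per-sample mean dCt, ddCt and relative
#'   expression), `replicates` (per-replicate dCt), and when `tukey`,
#'   `anova_p` and `tukey` (the [TukeyHSD()] table).
#' @export
qpcr_knockdown <- function(ct, target = NULL, reference = "GAPDH",
                           control = "NTC", tukey = TRUE) {
  stopifnot(is.data.frame(ct),
            all(c("sample", "gene", "replicate", "ct") %in% names(ct)))
  genes <- unique(ct$gene)
  if (is.null(target)) {
    target <- setdiff(genes, reference)
    if (length(target) != 1)
      stop("specify `target`: table contains ", length(target),
           " non-reference genes")
  }
  if (!reference %in% genes)
    stop("missing reference gene ", reference, " in Ct table")
  reps <- list()
  for (s in unique(ct$sample)) {
    st <- ct[ct$sample == s, ]
    for (r in unique(st$replicate)) {
      tgt <- st$ct[st$gene == target & st$replicate == r]
      ref <- st$ct[st$gene == reference & st$replicate == r]
      if (!length(ref))
        stop("missing reference (", reference, ") Ct for sample ", s,
             " replicate ", r)
      if (!length(tgt)) next
      reps[[length(reps) + 1L]] <- data.frame(
        sample = s, replicate = r, dct = tgt[1] - ref[1])
    }
  }
  reps <- do.call(rbind, reps)
  if (!control %in% reps$sample)
    stop("control sample '", control, "' missing from Ct table")
  dct_mean <- tapply(reps$dct, reps$sample, mean)
  ddct <- dct_mean - dct_mean[[control]]
  samples <- data.frame(sample = names(dct_mean),
                        n_replicates = as.integer(table(reps$sample)[names(dct_mean)]),
                        dct = as.numeric(dct_mean),
                        ddct = as.numeric(ddct),
                        relative_expression = 2^(-as.numeric(ddct)),
                        stringsAsFactors = FALSE)
  rownames(samples) <- NULL
  out <- list(target = target, reference = reference, control = control,
              samples = samples, replicates = reps)
  if (tukey && length(unique(reps$sample)) >= 2 &&
      any(table(reps$sample) >= 2)) {
    fit <- aov(dct ~ sample, data = transform(reps, sample = factor(sample)))
    out$anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    out$tukey <- TukeyHSD(fit)$sample
  }
  class(out) <- "qpcr_result"
  out
}

#' @export
print.qpcr_result <- function(x, ...) {
  cat(sprintf("<qpcr_result> %s vs %s, normalised to %s\n",
              x$target, x$reference, x$control))
  print(x$samples, digits = 4)
  if (!is.null(x$anova_p))
    cat(sprintf("one-way ANOVA p = %.3g (Tukey table in $tukey)\n",
                x$anova_p))
  invisible(x)
}

#' Simulate a tidy Ct table
#'
#' Draws replicate Ct values for a control and treated samples with given
#' true knockdown fractions; used to exercise the -delta-Ct pipeline.
#'
#' @param knockdown named numeric vector of true residual-expression
#'   fractions per treated sample (e.g. `c(siRNA1 = 0.2)` for an 80%
#'   knockdown).
#' @param n_replicates biological replicates (default 3).
#' @param sigma replicate standard deviation of Ct values.
#' @param seed integer seed.
#' @param base_ct_target,base_ct_ref baseline mean Ct of target and
#'   reference in the control sample.
#' @return tidy data.frame `sample`, `gene`, `replicate`, `ct`.
#' @export
simulate_ct_table <- function(knockdown, n_replicates = 3, sigma = 0.2,
                              seed = 1, base_ct_target = 24,
                              base_ct_ref = 18) {
  with_seed(seed, {
    samples <- c(NTC = 1.0, knockdown)
    rows <- list()
    for (s in names(samples)) {
      shift <- -log2(samples[[s]])     # knockdown raises target Ct
      for (r in seq_len(n_replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, gene = "TARGET", replicate = r,
          ct = rnorm(1, base_ct_target + shift, sigma))
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, gene = "GAPDH", replicate = r,
          ct = rnorm(1, base_ct_ref, sigma))
      }
    }
    do.call(rbind, rows)
  })
}
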