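readout_column <- function(readout = c("rc", "sum", "absdiff",
                                       "totalinput")) {
  readout <- match.arg(readout)
  switch(readout, rc = "rc", sum = "rc_sum", absdiff = "rc_absdiff",
         totalinput = "rc_totalinput")
}

decided <- function(table) {
  need <- c("session_id", "coherence_pct", "choice", "correct")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  table[table$choice != "none" & !is.na(table$correct), , drop = FALSE]
}

session_se <- function(values, sessions) {
  m <- tapply(values, sessions, mean, na.rm = TRUE)
  m <- m[!is.na(m)]
  if (length(m) < 2L) return(NA_real_)
  stats::sd(m) / sqrt(length(m))
}

#' Accuracy as a function of confidence
#'
#' Bins decided trials by quantiles of a confidence readout (pooled across
#' coherences) and reports the accuracy of each bin, with standard errors
#' over sessions. In a circuit whose confidence pool tracks decision
#' confidence, accuracy increases across confidence bins.
#'
#' @param table a `trial_table` from [run_experiment()]
#' @param readout which readout to bin on: `"rc"` (confidence pool),
#'   `"sum"` (summed decision rates), `"absdiff"` (absolute decision-rate
#'   difference) or `"totalinput"` (total decision-module input)
#' @param n_bins number of quantile bins (default 5)
#' @return A data frame with one row per bin: `bin`, `lo`, `hi`
#'   (quantile edges), `accuracy`, `se` (over sessions) and `n`. Bins that
#'   receive no trials are returned with `accuracy = NA` and flagged in
#'   the `empty` column.
#' @examples
#' tab <- data.frame(session_id = 1, coherence_pct = 0, choice = "A",
#'                   correct = rep(c(TRUE, FALSE), 10),
#'                   rc = rep(c(2, 1), 10))
#' accuracy_by_confidence(tab, n_bins = 2)
#' @export
accuracy_by_confidence <- function(table, readout = "rc", n_bins = 5) {
  col <- readout_column(readout)
  d <- decided(table)
  v <- d[[col]]
  if (!length(v)) stop("no decided trials to bin", call. = FALSE)
  edges <- stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1),
                           names = FALSE, type = 7)
  edges <- unique(edges)
  bins <- cut(v, breaks = edges, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(bin = seq_len(n_bins), lo = NA_real_, hi = NA_real_,
                    accuracy = NA_real_, se = NA_real_, n = 0L,
                    empty = TRUE)
  for (b in seq_len(length(edges) - 1L)) {
    sel <- bins == b
    out$lo[b] <- edges[b]; out$hi[b] <- edges[b + 1L]
    out$n[b] <- sum(sel)
    if (out$n[b] > 0L) {
      out$accuracy[b] <- mean(d$correct[sel])
      out$se[b] <- session_se(as.numeric(d$correct[sel]),
                              d$session_id[sel])
      out$empty[b] <- FALSE
    }
  }
  out
}

#' Folded-X summary: confidence by coherence, split by correctness
#'
#' Mean confidence readout per coherence level, separately for correct and
#' error trials, with standard errors over sessions. The behavioural
#' signature of confidence is the "folded X": on correct trials confidence
#' rises with evidence strength, on error trials it falls. Cells with
#' fewer than `min_n` trials (error trials vanish at high coherence) are
#' flagged.
#'
#' @inheritParams accuracy_by_confidence
#' @param min_n minimum trials for a cell to be considered estimable
#' @return A data frame with `coherence_pct`, `correct`, `mean`, `se`,
#'   `n`, `flagged`.
#' @examples
#' tab <- expand.grid(session_id = 1:2, coherence_pct = c(0, 10, 20),
#'                    correct = c(TRUE, FALSE))
#' tab$choice <- "A"
#' tab$rc <- ifelse(tab$correct, tab$coherence_pct, -tab$coherence_pct)
#' folded_x(tab)
#' @export
folded_x <- function(table, readout = "rc", min_n = 2) {
  col <- readout_column(readout)
  d <- decided(table)
  cohs <- sort(unique(d$coherence_pct))
  grid <- expand.grid(coherence_pct = cohs, correct = c(TRUE, FALSE))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- d$coherence_pct == grid$coherence_pct[i] &
      d$correct == grid$correct[i]
    n <- sum(sel)
    data.frame(coherence_pct = grid$coherence_pct[i],
               correct = grid$correct[i],
               mean = if (n) mean(d[[col]][sel]) else NA_real_,
               se = if (n) session_se(d[[col]][sel], d$session_id[sel])
                    else NA_real_,
               n = n, flagged = n < min_n)
  })
  do.call(rbind, res)
}

#' Permutation test for the folded-X branch trends
#'
#' Tests whether the correct-trial branch of [folded_x()] increases with
#' coherence and the error-trial branch decreases. For each branch the
#' statistic is the trial-level Spearman correlation between the readout
#' and coherence; the null distribution is generated by shuffling the
#' readout values against the coherence labels within that branch, which
#' destroys any readout--coherence association while preserving both
#' marginals. P-values are one-sided: increasing for the correct branch,
#' decreasing for the error branch.
#'
#' @inheritParams folded_x
#' @param n_perm number of permutations per branch
#' @param seed seed for the permutation stream
#' @return A list with `rho_correct`, `rho_error`, `p_correct`, `p_error`
#'   and `n_perm`.
#' @export
folded_x_permutation_test <- function(table, readout = "rc",
                                      n_perm = 1000, seed = 1) {
  col <- readout_column(readout)
  d <- decided(table)
  if (length(unique(d$coherence_pct)) < 3L)
    stop("need at least 3 coherence levels for a trend test",
         call. = FALSE)
  branch_test <- function(sub, side) {
    if (nrow(sub) < 3L || length(unique(sub$coherence_pct)) < 2L)
      return(list(rho = NA_real_, p = NA_real_))
    rho <- suppressWarnings(stats::cor(sub[[col]], sub$coherence_pct,
                                       method = "spearman"))
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      rp <- suppressWarnings(stats::cor(sample(sub[[col]]),
                                        sub$coherence_pct,
                                        method = "spearman"))
      hit <- if (side > 0) rp >= rho - 1e-12 else rp <= rho + 1e-12
      if (hit) cnt <- cnt + 1L
    }
    list(rho = rho, p = (1 + cnt) / (1 + n_perm))
  }
  set.seed(seed)
  tc <- branch_test(d[d$correct, , drop = FALSE], side = +1)
  te <- branch_test(d[!d$correct, , drop = FALSE], side = -1)
  list(rho_correct = tc$rho, rho_error = te$rho,
       p_correct = tc$p, p_error = te$p, n_perm = n_perm)
}

#' Psychometric curves split by confidence level
#'
#' Splits decided trials into high- and low-confidence halves at the
#' within-coherence median of the readout (so the split is not confounded
#' by the readout's dependence on coherence; with an odd cell count the
#' median trial joins the low half), then reports accuracy against
#' coherence for each half with session standard errors. A confidence
#' signal predicts accuracy beyond the stimulus: the high-confidence curve
#' lies above the low-confidence one.
#'
#' @inheritParams accuracy_by_confidence
#' @param split `"within"` (default, within-coherence median) or
#'   `"global"` (single pooled median)
#' @return A data frame with `coherence_pct`, `confidence` (`"high"` /
#'   `"low"`), `accuracy`, `se`, `n`.
#' @export
psychometric_by_confidence <- function(table, readout = "rc",
                                       split = c("within", "global")) {
  split <- match.arg(split)
  col <- readout_column(readout)
  d <- decided(table)
  d$high <- FALSE
  if (split == "global") {
    ord <- order(d[[col]])
    n_low <- ceiling(nrow(d) / 2)
    d$high[ord[seq_len(nrow(d)) > n_low]] <- TRUE
  } else {
    for (cc in unique(d$coherence_pct)) {
      ix <- which(d$coherence_pct == cc)
      ord <- ix[order(d[[col]][ix])]
      n_low <- ceiling(length(ix) / 2)
      if (length(ix) > n_low) d$high[ord[(n_low + 1):length(ix)]] <- TRUE
    }
  }
  cohs <- sort(unique(d$coherence_pct))
  grid <- expand.grid(coherence_pct = cohs, confidence = c("high", "low"),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- d$coherence_pct == grid$coherence_pct[i] &
      d$high == (grid$confidence[i] == "high")
    n <- sum(sel)
    data.frame(coherence_pct = grid$coherence_pct[i],
               confidence = grid$confidence[i],
               accuracy = if (n) mean(d$correct[sel]) else NA_real_,
               se = if (n) session_se(as.numeric(d$correct[sel]),
                                      d$session_id[sel]) else NA_real_,
               n = n)
  })
  do.call(rbind, res)
}

#' Relative confidence
#'
#' Subtracts the zero-coherence mean from every coherence level's mean
#' confidence, so that different adaptation strengths (which shift the
#' baseline firing rate) can be compared on a common footing. The value at
#' zero coherence is exactly zero.
#'
#' @param means per-coherence mean readout values
#' @param coherences matching coherence levels in percent; must include 0
#' @return Numeric vector of `means - means[coherences == 0]`.
#' @examples
#' relative_rc(c(5, 6, 8), c(0, 10, 20))
#' @export
relative_rc <- function(means, coherences) {
  if (length(means) != length(coherences))
    stop("means and coherences must have equal length", call. = FALSE)
  k <- which(coherences == 0)
  if (!length(k))
    stop("zero coherence must be present to define relative rc",
         call. = FALSE)
  means - means[k[1L]]
}

#' Confidence-coding slope
#'
#' The ordinary-least-squares slope of mean relative confidence against
#' coherence (percent), in Hz per percent coherence. A positive slope
#' means the confidence pool fires more for easier stimuli -- it codes
#' confidence; a zero slope means no coding.
#'
#' @param rel_rc per-coherence mean relative confidence, Hz
#' @param coherences matching coherence levels, percent
#' @return The slope (scalar), Hz per percent coherence.
#' @examples
#' coding_slope(c(0, 1, 2), c(0, 10, 20))   # 0.1
#' @export
coding_slope <- function(rel_rc, coherences) {
  if (length(rel_rc) < 2L || length(coherences) != length(rel_rc))
    stop("need at least two coherence levels", call. = FALSE)
  xc <- coherences - mean(coherences)
  sum(xc * (rel_rc - mean(rel_rc))) / sum(xc^2)
}

#' Mean confidence by coherence
#'
#' Convenience summary: per-coherence mean of a readout over decided
#' trials, with session standard errors.
#'
#' @inheritParams accuracy_by_confidence
#' @return Data frame with `coherence_pct`, `mean`, `se`, `n`.
#' @export
mean_rc_by_coherence <- function(table, readout = "rc") {
  col <- readout_column(readout)
  d <- decided(table)
  cohs <- sort(unique(d$coherence_pct))
  res <- lapply(cohs, function(cc) {
    sel <- d$coherence_pct == cc
    data.frame(coherence_pct = cc, mean = mean(d[[col]][sel]),
               se = session_se(d[[col]][sel], d$session_id[sel]),
               n = sum(sel))
  })
  do.call(rbind, res)
}

#' Compare candidate confidence readouts
#'
#' Runs the folded-X permutation test for each of the four readouts and
#' reports which of them carry the confidence signature (correct branch
#' increasing, error branch decreasing). In the default parameter regime
#' the confidence-pool rate and the absolute decision-rate difference pass
#' while the summed rates and the total decision-module input do not.
#'
#' @inheritParams folded_x_permutation_test
#' @param alpha significance level for calling a branch trend present
#' @return A data frame with one row per readout: the branch correlations,
#'   p-values, and a logical `passes` column.
#' @export
readout_contrast <- function(table, n_perm = 500, seed = 1,
                             alpha = 0.05) {
  readouts <- c("rc", "sum", "absdiff", "totalinput")
  res <- lapply(readouts, function(r) {
    tst <- folded_x_permutation_test(table, readout = r, n_perm = n_perm,
                                     seed = seed)
    data.frame(readout = r, rho_correct = tst$rho_correct,
               rho_error = tst$rho_error, p_correct = tst$p_correct,
               p_error = tst$p_error,
               passes = tst$p_correct < alpha & tst$p_error < alpha &
                 tst$rho_correct > 0 & tst$rho_error < 0)
  })
  do.call(rbind, res)
}
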