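#' Fully within-subject 2 x 2 x 2 repeated-measures ANOVA
#'
#' Each of the seven effects (three mains, three two-way interactions, one
#' three-way) is tested against its own effect-by-subject interaction mean
#' square, with 1 and N - 1 degrees of freedom; all factors having two levels
#' makes sphericity moot. Partial eta-squared is
#' `SS_effect / (SS_effect + SS_error)` with the error of the effect's own
#' stratum. Fitting is done with [stats::aov()] and an
#' `Error(subject/(A*B*C))` stratum design.
#'
#' @param df Data.frame in long format: one row per subject x cell of a
#'   complete, balanced 2 x 2 x 2 within-subject design.
#' @param value,subject Column names of the response and the subject id.
#' @param factors Character vector of the three factor column names.
#' @return Data.frame with one row per effect: `effect`, `df1`, `df2`, `F`,
#'   `p`, `pes`.
#' @export
rm_anova_2x2x2 <- function(df, value = "value", subject = "subject",
                           factors = c("A", "B", "C")) {
  stopifnot(length(factors) == 3, all(c(value, subject, factors) %in% names(df)))
  d <- df[, c(value, subject, factors)]
  names(d) <- c(".y", ".s", "A", "B", "C")
  d$.s <- factor(d$.s)
  for (f in c("A", "B", "C")) {
    d[[f]] <- factor(d[[f]])
    if (nlevels(d[[f]]) != 2) stop("factor ", f, " must have two levels")
  }
  n_sub <- nlevels(d$.s)
  if (n_sub < 2) stop("need at least 2 subjects")
  if (nrow(d) != n_sub * 8 || any(table(d$.s, interaction(d$A, d$B, d$C)) != 1)) {
    stop("design must be complete and balanced: one observation per ",
         "subject and cell")
  }
  fit <- stats::aov(.y ~ A * B * C + Error(.s / (A * B * C)), data = d)
  sm <- summary(fit)
  effects <- c("A", "B", "C", "A:B", "A:C", "B:C", "A:B:C")
  rows <- lapply(effects, function(eff) {
    stratum <- sm[[paste0("Error: .s:", eff)]][[1]]
    terms <- trimws(rownames(stratum))
    ss_eff <- stratum[terms == eff, "Sum Sq"]
    ss_err <- stratum[terms == "Residuals", "Sum Sq"]
    if (ss_err <= 0) stop("zero error sum of squares for effect ", eff)
    f_val <- stratum[terms == eff, "F value"]
    data.frame(effect = eff,
               df1 = stratum[terms == eff, "Df"],
               df2 = stratum[terms == "Residuals", "Df"],
               F = f_val,
               p = stratum[terms == eff, "Pr(>F)"],
               pes = ss_eff / (ss_eff + ss_err))
  })
  out <- do.call(rbind, rows)
  out$effect <- vapply(strsplit(out$effect, ":"), function(parts) {
    paste(factors[match(parts, c("A", "B", "C"))], collapse = ":")
  }, character(1))
  rownames(out) <- NULL
  out
}

#' Two-tailed within-subject (paired) t-test
#'
#' `t = mean(d) / (SD(d) / sqrt(N))` over the paired differences, two-tailed
#' p from the t distribution with N - 1 df (via [stats::t.test()]).
#'
#' Identical pairs (`x == y` everywhere) return the degenerate but
#' well-defined `t = 0, p = 1`; constant nonzero differences have no valid
#' t statistic and raise an error.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = length(d) - 1, p = 1))
    stop("zero-variance differences")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Significance decision at a fixed threshold
#'
#' Rejects iff `p < alpha` (strict inequality).
#'
#' @param p p-value in (0, 1].
#' @param alpha Significance threshold (default 0.05).
#' @return Logical.
#' @export
decide <- function(p, alpha = 0.05) {
  stopifnot(p > 0, p <= 1)
  p < alpha
}

#' Assemble ANOVA input from study-level tonic tables
#'
#' Restricts a row-bound multi-participant `tonic_table` (after
#' [first_last_reduce()]) to one stimulus type and recodes the design into
#' the factors of the repeated-measures analysis: PAM location, listening
#' condition (attention toward vs away from the PAM's side), and time (first
#' vs last segment).
#'
#' @param tab Data.frame with columns `participant`, `pam_side`, `stim_kind`,
#'   `attended_side`, `segment`, `z_amplitude`.
#' @param stim_kind `"tone_burst"` or `"chirp"`: the stimulus type delivered
#'   to the PAM's side.
#' @return Data.frame with `subject`, `pam`, `condition`, `time`, `value`.
#' @export
anova_input_from_tonic <- function(tab, stim_kind) {
  sub <- tab[tab$stim_kind == stim_kind, , drop = FALSE]
  data.frame(subject = sub$participant,
             pam = sub$pam_side,
             condition = ifelse(sub$attended_side == sub$pam_side,
                                "toward", "away"),
             time = sub$segment,
             value = sub$z_amplitude)
}
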