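# Independent oracles and shared fixtures for the test suite.

# Brute-force sum-of-squares decomposition of a fully within-subject 2x2x2
# design (one observation per subject and cell), written directly from the
# textbook marginal-means decomposition; independent of rm_anova_2x2x2().
oracle_rm_anova <- function(y) {
  # y: array [subject, A, B, C] with dims c(S, 2, 2, 2)
  S <- dim(y)[1]
  gm <- mean(y)
  m_s <- apply(y, 1, mean)
  eff <- list(A = 2, B = 3, C = 4, `A:B` = c(2, 3), `A:C` = c(2, 4),
              `B:C` = c(3, 4), `A:B:C` = c(2, 3, 4))
  out <- list()
  for (nm in names(eff)) {
    dims <- eff[[nm]]
    # effect estimate per cell of the involved factors, from marginal means
    # via inclusion-exclusion over subsets
    cell_effect <- function(means_fun) {
      subsets <- unlist(lapply(0:length(dims), function(k) {
        if (k == 0) return(list(integer(0)))
        lapply(utils::combn(seq_along(dims), k, simplify = FALSE),
               function(ii) dims[ii])
      }), recursive = FALSE)
      tot <- 0
      for (ss in subsets) {
        sign <- (-1)^(length(dims) - length(ss))
        tot <- tot + sign * means_fun(ss)
      }
      tot
    }
    # SS_effect: S * levels-product * sum over effect cells of squared effect
    marg <- function(ss) {
      if (length(ss) == 0) return(array(gm, dim = rep(2, length(dims))))
      m <- apply(y, ss, mean)
      # broadcast to the full effect grid
      perm_dims <- match(ss, dims)
      full <- array(0, dim = rep(2, length(dims)))
      idx <- as.matrix(expand.grid(rep(list(1:2), length(dims))))
      full[idx] <- m[idx[, perm_dims, drop = FALSE]]
      full
    }
    effect_cells <- cell_effect(marg)
    n_per_cell <- S * 8 / (2^length(dims))
    ss_eff <- n_per_cell * sum(effect_cells^2)
    # SS_{effect x subject}: same decomposition within each subject, around
    # the subject mean
    ss_int <- 0
    for (s in 1:S) {
      ys <- y[s, , , , drop = FALSE]
      dim(ys) <- c(1, 2, 2, 2)
      gm_s <- m_s[s]
      marg_s <- function(ss) {
        if (length(ss) == 0) return(array(gm_s, dim = rep(2, length(dims))))
        m <- apply(ys, ss, mean)
        perm_dims <- match(ss, dims)
        full <- array(0, dim = rep(2, length(dims)))
        idx <- as.matrix(expand.grid(rep(list(1:2), length(dims))))
        full[idx] <- m[idx[, perm_dims, drop = FALSE]]
        full
      }
      dev <- cell_effect(marg_s) - effect_cells
      ss_int <- ss_int + (8 / (2^length(dims))) * sum(dev^2)
    }
    f_val <- (ss_eff / 1) / (ss_int / (S - 1))
    out[[nm]] <- data.frame(
      effect = nm, df1 = 1, df2 = S - 1, F = f_val,
      p = stats::pf(f_val, 1, S - 1, lower.tail = FALSE),
      pes = ss_eff / (ss_eff + ss_int))
  }
  do.call(rbind, out)
}

# long-format data.frame from a [subject, A, B, C] array, matching the
# rm_anova_2x2x2() input contract
anova_df_from_array <- function(y) {
  S <- dim(y)[1]
  g <- expand.grid(subject = 1:S, A = c("a1", "a2"), B = c("b1", "b2"),
                   C = c("c1", "c2"), stringsAsFactors = FALSE)
  g$value <- as.vector(y)
  g
}

# per-subject contrast for one effect of the 2x2x2 design: mean of +cells
# minus mean of -cells (two-level factors, so F = t^2 on this contrast)
effect_contrast <- function(y, effect) {
  signs <- list(A = c(2), B = c(3), C = c(4), `A:B` = c(2, 3),
                `A:C` = c(2, 4), `B:C` = c(3, 4), `A:B:C` = c(2, 3, 4))
  dims <- signs[[effect]]
  idx <- as.matrix(expand.grid(1:2, 1:2, 1:2))
  s <- apply(idx[, dims - 1, drop = FALSE], 1, function(v) {
    prod(ifelse(v == 1, 1, -1))
  })
  vapply(seq_len(dim(y)[1]), function(subj) {
    vals <- as.vector(y[subj, , , ])
    mean(vals[s > 0]) - mean(vals[s < 0])
  }, numeric(1))
}

# reduced filter/config fixtures shared by the simulation-backed tests
test_fspec <- function() {
  filter_spec(bandpass_hz = c(20, 250), fir_order = 600, target_rate = 600)
}

test_params <- function(...) {
  emg_model_params(rate = 1200, noise_band_hz = c(20, 250), ...)
}
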