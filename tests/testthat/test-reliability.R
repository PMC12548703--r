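mk_epochs <- function(cols, time_ms) {
  do.call(cbind, cols)
}

test_that("split-half correlation handles identical, inverted and flat averages", {
  rate <- 600
  time_ms <- seq(-100, 100 - 1000 / rate, by = 1000 / rate)
  bump <- exp(-((time_ms - 15)^2) / 40)
  # odd set identical to even set
  ep <- cbind(bump, bump, bump, bump)
  expect_equal(half_split_r(ep, time_ms), 1)
  # even average = -(odd average)
  ep2 <- cbind(bump, -bump)
  expect_equal(half_split_r(ep2, time_ms), -1)
  # flat averages -> undefined, sentinel -Inf
  ep3 <- cbind(rep(1, length(time_ms)), rep(2, length(time_ms)))
  expect_identical(half_split_r(ep3, time_ms), -Inf)
  expect_error(half_split_r(ep3[, 1, drop = FALSE], time_ms))
  # unequal counts allowed: 5 epochs -> 3 + 2 split
  ep5 <- cbind(bump, bump, bump, bump, bump)
  expect_equal(half_split_r(ep5, time_ms), 1)
})

test_that("independent white-noise epochs give near-zero mean correlation", {
  rate <- 600
  time_ms <- seq(-100, 100 - 1000 / rate, by = 1000 / rate)
  set.seed(7)
  rs <- replicate(400, {
    half_split_r(matrix(stats::rnorm(length(time_ms) * 10), ncol = 10),
                 time_ms)
  })
  expect_lt(abs(mean(rs)), 3 * stats::sd(rs) / sqrt(length(rs)))
})

test_that("certification applies the inclusive 6-of-8 rule over standard cells", {
  rate <- 600
  time_ms <- seq(-100, 100 - 1000 / rate, by = 1000 / rate)
  bump <- exp(-((time_ms - 15)^2) / 40)
  # build a cell with a prescribed split-half r by mixing bump and noise
  cell_with_r <- function(r_target, seed) {
    set.seed(seed)
    if (r_target >= 0.999) return(cbind(bump, bump))
    # two "averages" with correlation r: a shared component plus orthogonal
    # noise; epochs equal to their set averages
    shared <- bump / stats::sd(bump)
    n1 <- stats::rnorm(length(bump)); n1 <- stats::resid(stats::lm(n1 ~ shared))
    n2 <- stats::rnorm(length(bump)); n2 <- stats::resid(stats::lm(n2 ~ shared))
    lam <- sqrt(r_target / (1 - r_target))
    a1 <- lam * shared + n1 / stats::sd(n1)
    a2 <- lam * shared + n2 / stats::sd(n2)
    cbind(a1, a2)
  }
  build_sets <- function(rs) {
    cells <- expand.grid(pam = c("left", "right"),
                         stim = c("left", "right"),
                         att = c("left", "right"), stringsAsFactors = FALSE)
    sets <- list()
    for (pam in c("left", "right")) {
      sub <- cells[cells$pam == pam, ]
      eps <- list(); labs <- list()
      for (i in seq_len(nrow(sub))) {
        k <- which(cells$pam == pam)[i]
        eps[[i]] <- cell_with_r(rs[k], seed = 50 + k)
        labs[[i]] <- data.frame(stim_side = rep(sub$stim[i], 2),
                                attended_side = rep(sub$att[i], 2))
      }
      sets[[pam]] <- structure(list(epochs = do.call(cbind, eps),
                                    time_ms = time_ms, rate = rate,
                                    labels = do.call(rbind, labs)),
                               class = "epoch_set")
    }
    sets
  }
  # all 8 cells correlated -> pass
  rep1 <- certify_participant(build_sets(rep(0.9999, 8)), participant = 1)
  expect_true(rep1$passed)
  expect_equal(rep1$n_pass, 8)
  # only 5 strong cells -> fail even if they are excellent
  rs <- c(rep(0.9999, 5), rep(0, 3))
  rep2 <- certify_participant(build_sets(rs), participant = 2)
  expect_false(rep2$passed)
  # boundary: a threshold exactly equal to a cell's r still counts that cell
  # (criterion is inclusive, "0.4 or higher")
  r_obs <- as.numeric(rep1[1, grep("^r_", names(rep1))])
  rep3 <- certify_participant(build_sets(rep(0.9999, 8)),
                              r_threshold = min(r_obs), min_pass = 8)
  expect_true(rep3$passed)
  expect_equal(rep3$n_pass, 8)
})

test_that("certification is stable under epoch-order permutation with a strong reflex", {
  rate <- 600
  time_ms <- seq(-100, 100 - 1000 / rate, by = 1000 / rate)
  bump <- exp(-((time_ms - 15)^2) / 40)
  set.seed(17)
  cells <- expand.grid(pam = c("left", "right"), stim = c("left", "right"),
                       att = c("left", "right"), stringsAsFactors = FALSE)
  # 30 noisy reflex epochs per cell; averaging 15 leaves the template clear
  epochs_per_cell <- lapply(seq_len(nrow(cells)), function(i) {
    sapply(1:30, function(j) {
      stats::rlnorm(1, 0, 0.3) * bump + stats::rnorm(length(bump), 0, 0.8)
    })
  })
  build <- function(perm_seed = NULL) {
    sets <- list()
    for (pam in c("left", "right")) {
      rows <- which(cells$pam == pam)
      eps <- lapply(rows, function(k) {
        e <- epochs_per_cell[[k]]
        if (!is.null(perm_seed)) {
          set.seed(perm_seed + k)
          e <- e[, sample(ncol(e))]
        }
        e
      })
      labs <- lapply(rows, function(k) {
        data.frame(stim_side = rep(cells$stim[k], 30),
                   attended_side = rep(cells$att[k], 30))
      })
      sets[[pam]] <- structure(list(epochs = do.call(cbind, eps),
                                    time_ms = time_ms, rate = rate,
                                    labels = do.call(rbind, labs)),
                               class = "epoch_set")
    }
    sets
  }
  base_pass <- certify_participant(build(), participant = 1)$passed
  expect_true(base_pass)
  perms <- vapply(1:10, function(s) {
    certify_participant(build(perm_seed = 100 * s), participant = 1)$passed
  }, logical(1))
  expect_gte(mean(perms == base_pass), 0.9)
})

test_that("inclusive threshold and missing cells are enforced", {
  rate <- 600
  time_ms <- seq(-100, 100 - 1000 / rate, by = 1000 / rate)
  bump <- exp(-((time_ms - 15)^2) / 40)
  labs <- data.frame(stim_side = c("left", "left"),
                     attended_side = c("left", "left"))
  es <- structure(list(epochs = cbind(bump, bump), time_ms = time_ms,
                       rate = rate, labels = labs), class = "epoch_set")
  expect_error(certify_participant(list(left = es, right = es)),
               "missing cell")
})
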