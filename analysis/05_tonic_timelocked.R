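#!/usr/bin/env Rscript
# Secondary tonic analysis (time-locked activity): baseline-normalized
# rectified chirp-locked waveforms per PAM and listening condition, and the
# within-subject toward/away pre-stimulus contrasts for standard and deviant
# chirps.

suppressPackageStartupMessages({
  library(pamtonic)
  library(ggplot2)
})
dir.create("results", showWarnings = FALSE)

if (!file.exists("results/study_run.rds")) {
  stop("run analysis/03_preprocess_certify.R first")
}
res <- readRDS("results/study_run.rds")

# tidy export of the normalized averages (grand average over participants)
rows <- list()
for (j in seq_along(res$timelocked)) {
  tl <- res$timelocked[[j]]
  for (pam in c("left", "right")) {
    w <- tl$norm[[pam]]
    for (cl in colnames(w$waveforms)) {
      parts <- strsplit(cl, "_")[[1]]
      rows[[length(rows) + 1]] <- data.frame(
        participant = res$included[j], pam_side = pam,
        attended_side = parts[1], chirp_kind = parts[2],
        time_ms = w$time_ms, normalized_amplitude = w$waveforms[, cl])
    }
  }
}
wave_df <- do.call(rbind, rows)
write.csv(wave_df, "results/timelocked_waveforms.csv", row.names = FALSE)

ga <- aggregate(normalized_amplitude ~ pam_side + attended_side +
                  chirp_kind + time_ms, data = wave_df, FUN = mean)
ga$line <- paste(ga$pam_side, "PAM /", ga$attended_side, "attended")
p <- ggplot(ga, aes(time_ms, normalized_amplitude, colour = line)) +
  geom_line() + facet_wrap(~chirp_kind) +
  labs(x = "time re chirp offset (ms)",
       y = "baseline-normalized rectified amplitude (z)",
       colour = NULL,
       title = "Chirp-locked rectified PAM activity") +
  theme_minimal()
ggsave("results/timelocked_waveforms.pdf", p, width = 9, height = 4)

write.csv(res$prestim, "results/prestim_contrasts.csv", row.names = FALSE)
cat("pre-stimulus toward/away contrasts (within-subject t-tests):\n")
for (cls in names(res$t_tests)) {
  tt <- res$t_tests[[cls]]
  cat(sprintf("  %-8s t(%d) = %.2f, p = %.3g\n", cls, tt$df, tt$t, tt$p))
}
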