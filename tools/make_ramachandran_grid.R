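# Generates inst/extdata/ramachandran_regions.tsv: a simplified PROCHECK-style
# 10x10 degree region map. Regions are elliptical basins (torus metric) around
# the right-handed alpha, beta and left-handed alpha centres, with a hard
# steric exclusion band near phi = 0; labels F/A/G/D = favored /
# additionally_allowed / generously_allowed / disallowed.

wrap180 <- function(x) ((x + 180) %% 360) - 180

regions <- list(
  list(phi = -63, psi = -43, a = 35, b = 45),   # right-handed alpha
  list(phi = -115, psi = 130, a = 55, b = 60),  # beta / extended
  list(phi = 60, psi = 45, a = 25, b = 30)      # left-handed alpha
)

label <- function(phi, psi) {
  if (abs(phi) < 25) return("D")  # steric clash band around phi = 0
  d <- vapply(regions, function(r) {
    sqrt((wrap180(phi - r$phi) / r$a)^2 + (wrap180(psi - r$psi) / r$b)^2)
  }, numeric(1))
  dm <- min(d)
  if (dm <= 1) "F" else if (dm <= 1.6) "A" else if (dm <= 2.2) "G" else "D"
}

ctr <- seq(-175, 175, by = 10)
grid <- expand.grid(phi = ctr, psi = ctr)
grid$region <- mapply(label, grid$phi, grid$psi)
write.table(grid, "inst/extdata/ramachandran_regions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", nrow(grid), "cells\n")
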