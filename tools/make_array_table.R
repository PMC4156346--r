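# Regenerates inst/extdata/gradient_array_100.csv: the bundled 100-gradient
# array taxonomy (20 ordered + 80 random; linear, exponential and
# sinusoid-superposed profiles, densities 0.0002-0.4444, 400x400 um fields).
pairs <- list(c(0.0002, 0.4444), c(0.001, 0.4444), c(0.002, 0.40),
              c(0.005, 0.35), c(0.01, 0.30), c(0.01, 0.20),
              c(0.02, 0.30), c(0.02, 0.20), c(0.05, 0.30), c(0.10, 0.30))
rows <- list()
add <- function(id, kind, algorithm, D_min, D_max, k = NA, A = NA, B = NA,
                k1 = NA, k2 = NA) {
  rows[[length(rows) + 1]] <<- data.frame(
    id = id, kind = kind, algorithm = algorithm, D_min = D_min,
    D_max = D_max, k = k, A = A, B = B, k1 = k1, k2 = k2,
    W = 400, L = 400, dot_edge = 0.2, box_width = 1, seed = 100 + id)
}
for (i in 1:10) add(i, "linear", "ordered", pairs[[i]][1], pairs[[i]][2])
for (i in 1:10) add(10 + i, "exponential", "ordered",
                    pairs[[i]][1], pairs[[i]][2], k = 3)
# 21-30: zero-slope sinusoids, linearly growing amplitude (controls)
lev <- seq(0.10, 0.28, length.out = 10)
amp <- rep(c(0.02, 0.05, 0.08, 0.10, 0.06), 2)
freq <- rep(c(4, 8, 12, 16, 22), each = 2)
for (i in 1:10) add(20 + i, "sinusoid_flat", "random", lev[i], lev[i],
                    A = amp[i], B = freq[i], k2 = 0)
# 31-34: zero-slope sinusoids, constant amplitude (controls)
for (i in 1:4) add(30 + i, "sinusoid_flat", "random",
                   c(0.12, 0.16, 0.20, 0.24)[i], c(0.12, 0.16, 0.20, 0.24)[i],
                   A = c(0.04, 0.06, 0.08, 0.10)[i], B = c(6, 10, 14, 18)[i])
# 35-36: linear trend + linearly growing amplitude
add(35, "sinusoid_linear_trend", "random", 0.01, 0.30, A = 0.05, B = 10, k2 = 0)
add(36, "sinusoid_linear_trend", "random", 0.02, 0.40, A = 0.08, B = 15, k2 = 0)
# 37-40: exponential trend + exponentially growing amplitude
add(37, "sinusoid_exponential_trend", "random", 0.01, 0.30, A = 0.10, B = 20,
    k1 = 3, k2 = 3)
add(38, "sinusoid_exponential_trend", "random", 0.01, 0.30, A = 0.05, B = 10,
    k1 = 3, k2 = 3)
add(39, "sinusoid_exponential_trend", "random", 0.02, 0.40, A = 0.08, B = 15,
    k1 = 3, k2 = 3)
add(40, "sinusoid_exponential_trend", "random", 0.005, 0.35, A = 0.06, B = 12,
    k1 = 3, k2 = 3)
# 41-60: linear trend + constant-amplitude sinusoid
A41 <- rep(c(0.02, 0.04, 0.06, 0.08), 5)
B41 <- rep(c(5, 8, 12, 16, 20), each = 4)
for (i in 1:20) add(40 + i, "sinusoid_linear_trend", "random",
                    0.01 + 0.01 * (i %% 3), 0.25 + 0.01 * (i %% 5),
                    A = A41[i], B = B41[i])
# 61-80: exponential trend + constant-amplitude sinusoid
for (i in 1:20) add(60 + i, "sinusoid_exponential_trend", "random",
                    0.01 + 0.01 * (i %% 3), 0.25 + 0.01 * (i %% 5),
                    A = A41[i], B = B41[i], k1 = 3)
for (i in 1:10) add(80 + i, "linear", "random", pairs[[i]][1], pairs[[i]][2])
for (i in 1:10) add(90 + i, "exponential", "random",
                    pairs[[i]][1], pairs[[i]][2], k = 3)
tab <- do.call(rbind, rows)
stopifnot(nrow(tab) == 100, !anyDuplicated(tab$id))
write.csv(tab, "inst/extdata/gradient_array_100.csv", row.names = FALSE,
          quote = FALSE, na = "")
cat("wrote", nrow(tab), "rows\n")
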