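# small deterministic fixtures built in code

random_table <- function(n = 3L, m = 4L, seed = 1L, subject = "s01",
                         space = "cortex_parcel") {
  set.seed(seed)
  activity_table(matrix(rnorm(n * m), n, m),
                 sprintf("cond%02d", seq_len(n)),
                 sprintf("u%02d", seq_len(m)),
                 subject_id = subject, space = space)
}

# brute-force one-way RM-ANOVA straight from the definitional sums over
# cells (independent of the package implementation)
oneway_anova_bruteforce <- function(y) {
  S <- nrow(y); N <- ncol(y)
  grand <- mean(y)
  ss_total <- 0; ss_subj <- 0; ss_cond <- 0
  for (s in seq_len(S)) ss_subj <- ss_subj + N * (mean(y[s, ]) - grand)^2
  for (c in seq_len(N)) ss_cond <- ss_cond + S * (mean(y[, c]) - grand)^2
  for (s in seq_len(S)) for (c in seq_len(N)) {
    ss_total <- ss_total + (y[s, c] - grand)^2
  }
  ss_err <- ss_total - ss_subj - ss_cond
  df1 <- N - 1; df2 <- (N - 1) * (S - 1)
  f <- (ss_cond / df1) / (ss_err / df2)
  list(f = f, df1 = df1, df2 = df2,
       p = pf(f, df1, df2, lower.tail = FALSE),
       ss_cond = ss_cond, ss_err = ss_err)
}

# 2x3 within-subject factorial design over 6 conditions
design_2x3 <- function() {
  condition_design(sprintf("c%d", 1:6),
                   data.frame(phase = rep(c("enc", "ret"), 3),
                              load = rep(c("2", "4", "6"), each = 2)))
}

design_2x2x3 <- function() {
  grid <- expand.grid(phase = c("enc", "ret"), dir = c("fwd", "bwd"),
                      load = c("2", "4", "6"))
  condition_design(sprintf("c%02d", 1:12), grid)
}
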