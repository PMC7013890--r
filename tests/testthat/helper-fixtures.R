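# Small in-code fixtures shared across test files.

toy_coding <- function() {
  list(x1 = factor_coding("x1", 1:5),
       x2 = factor_coding("x2", 1:3))
}

# A hand-sized valid accident table.
toy_table <- function(fatalities = c(1, 0, 0, 2, 0, 0),
                      injuries  = c(0, 2, 0, 1, 3, 1)) {
  n <- length(fatalities)
  accident_table(
    data.frame(record_id = paste0("a", seq_len(n)),
               lon = seq(114.0, by = 0.01, length.out = n),
               lat = seq(22.5, by = 0.01, length.out = n),
               year = rep(2014:2016, length.out = n),
               fatalities = fatalities, injuries = injuries,
               x1 = rep(c(1L, 2L, 3L), length.out = n),
               x2 = rep(c(1L, 2L), length.out = n),
               stringsAsFactors = FALSE),
    toy_coding())
}

# Random outcome + stratum labels for property-style loops.
rand_instance <- function(n_max = 50, h_max = 5) {
  n <- sample(4:n_max, 1)
  h <- sample(2:h_max, 1)
  list(y = stats::rnorm(n),
       g = sample(letters[seq_len(h)], n, replace = TRUE))
}

# Independent one-way ANOVA oracle for q: between/total share = R^2.
anova_q_oracle <- function(y, g) {
  if (length(unique(g)) < 2) return(0)
  summary(stats::lm(y ~ factor(g)))$r.squared
}
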