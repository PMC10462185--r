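# Shared fixtures: all generated in code, no files.

# minimal 4-row CSV text: 2 animals x 2 times, labelled groups
csv_minimal <- function() {
  c("animal_id,group,time,volume",
    "a1,A,3,10",
    "a1,A,5,20",
    "b1,B,3,11",
    "b1,B,5,19")
}

# 5-row CSV with one NA volume
csv_with_na <- function() {
  c(csv_minimal(), "b1,B,7,NA")
}

# a small balanced study with k time points and n animals per group,
# volumes drawn lognormal around a growth trend
random_study <- function(n = 4, times = c(3, 5, 7), seed = 1) {
  set.seed(seed)
  id <- character(0); g <- integer(0); tt <- numeric(0); v <- numeric(0)
  for (gr in 0:1) {
    for (i in seq_len(n)) {
      id <- c(id, rep(sprintf("g%d_%d", gr, i), length(times)))
      g <- c(g, rep(gr, length(times)))
      tt <- c(tt, times)
      v <- c(v, exp(log(5) + 0.2 * times + rnorm(length(times), sd = 0.2)))
    }
  }
  study_table(id, g, tt, v)
}

# random well-conditioned pair with n0, n1 animals
random_pair <- function(n0 = 5, n1 = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  timepoint_pair(rnorm(n0, 10, 2), rnorm(n0, 20, 3),
                 rnorm(n1, 12, 2), rnorm(n1, 25, 3))
}
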