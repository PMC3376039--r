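# shared fixture builders for the suite; everything is generated in code

# a three-section specimen matching the worked arithmetic examples
make_specimen <- function(counts = c(1, 5, 4),
                          lengths = list(5, 6, 7),
                          sclerotic = rep(0, length(counts)),
                          gauge = 16) {
  secs <- Map(function(l, k, s) biopsy_section(l, k, s),
              lengths, counts, sclerotic)
  biopsy_specimen(secs, needle_gauge = gauge)
}

# Monte-Carlo oracle for the mean observed profile area: cut a sphere of
# radius r at offsets uniform in (-h, h) and average the circle areas
mc_profile_area <- function(r, r_o, n = 1e6, seed = 1) {
  set.seed(seed)
  h <- sqrt(r^2 - r_o^2)
  x <- runif(n, -h, h)
  a <- pi * (r^2 - x^2)
  list(mean = mean(a), se = sd(a) / sqrt(n))
}

# brute-force two-group log-rank: explicit 2x2 tabulation at each distinct
# event time (independent of the package's vectorised implementation)
brute_logrank <- function(time, status, group) {
  g <- group == unique(group)[1]
  ut <- sort(unique(time[status == 1]))
  U <- 0; V <- 0
  for (t in ut) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g)
    d <- sum(time == t & status == 1)
    d1 <- sum(time == t & status == 1 & g)
    U <- U + d1 - d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  c(U = U, V = V, chisq = if (V > 0) U^2 / V else 0)
}

extdata <- function(f) system.file("extdata", f, package = "nephest")
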