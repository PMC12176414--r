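# Fixture builders shared across the suite. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# small random image set with both classes present
makeTestSet <- function(n = 10, size = 12L, split = "test", seed = 42) {
  withr::with_seed(seed, {
    imgs <- replicate(n, matrix(sample(0:255, size * size, replace = TRUE),
                                size, size), simplify = FALSE)
    labs <- if (n >= 2) c(0L, 1L, sample(0:1, max(n - 2, 0), replace = TRUE))
            else 1L
    LabeledImageSet(imgs, labs, split = split)
  })
}

randomImage <- function(size = 16L, seed = 1) {
  withr::with_seed(seed,
    matrix(sample(0:255, size * size, replace = TRUE), size, size))
}

# toy linear scorer used as the analytic-gradient oracle for SPSA;
# score(x) = sum(w * x_unit)
setClass("ToyLinearScorer", representation(w = "numeric", dims = "numeric"))
setMethod("predictScores", "ToyLinearScorer", function(object, newdata, ...) {
  imgs <- if (is(newdata, "LabeledImageSet")) images(newdata)
          else if (is.matrix(newdata)) list(newdata) else newdata
  vapply(imgs, function(im) sum(object@w * (as.numeric(im) / 255)),
         numeric(1))
})
setMethod("predictLabels", "ToyLinearScorer", function(object, newdata, ...) {
  as.integer(predictScores(object, newdata) > 0)
})

# independent brute-force Wilcoxon signed-rank p by full subset
# enumeration over the 2^m sign assignments (test oracle; kept free of
# the package's dynamic-programming path)
bruteWilcoxP <- function(d, alternative) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  sums <- 0
  for (i in seq_len(m)) {
    sums <- c(sums, sums + r[i])  # all subset rank-sums, by accretion
  }
  pLess <- mean(sums <= W + 1e-9)
  pGreater <- mean(sums >= W - 1e-9)
  switch(alternative,
         less = pLess,
         greater = pGreater,
         two_sided = min(1, 2 * min(pLess, pGreater)))
}
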