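# Training-set variant construction and replicated test-set perturbation.
#
# Perturbed images always REPLACE their originals: set size, ids, ordering
# and labels are never changed by any builder. Exactly
# k = round(p * N / 100) images are perturbed (round half up; the protocol
# percentages need not be integral on a given set size).

#' @include AllClasses.R perturbations.R rng.R
NULL

roundHalfUp <- function(x) floor(x + 0.5)

# Builders record their random selections on the returned object
# (attributes "perturbedIndex", "perturbedGroups", "kindAssignments") so
# reports and tests can trace every replicate to its selection without
# re-deriving seeds.

# replace images at `idx` with their `kind`-perturbed versions; seeds are
# derived per image so any subset is reproducible independently
.perturbAt <- function(set, idx, kind, cfg, seed) {
  imgs <- set@images
  for (i in idx)
    imgs[[i]] <- applyPerturbation(imgs[[i]], kind, cfg,
                                   seed = childSeed(seed, "img", i))
  new("LabeledImageSet", images = imgs, labels = set@labels,
      ids = set@ids, split = set@split)
}

#' Build a partially perturbed training set
#'
#' Selects exactly \code{round(fractionP * N / 100)} training images
#' uniformly without replacement (under the spec's seed) and replaces each
#' by its perturbed version. Labels, ids, ordering and set size are
#' unchanged -- replacement, not augmentation, so the classifier sees the
#' same sample size as the clean baseline.
#'
#' @param train A nonempty \linkS4class{LabeledImageSet}.
#' @param spec A \linkS4class{TrainVariantSpec}.
#' @param cfg A \linkS4class{PerturbationConfig}.
#' @return A \linkS4class{LabeledImageSet} of the same size, with the
#'   chosen indices recorded in \code{attr(, "perturbedIndex")}.
#' @export
buildPerturbedTrainingSet <- function(train, spec,
                                      cfg = perturbationConfig()) {
  if (length(train) == 0L) stop("empty training set")
  if (spec@fractionP == 0) return(train)
  N <- length(train)
  k <- roundHalfUp(spec@fractionP * N / 100)
  idx <- withSeed(childSeed(spec@seed, "select"), sample.int(N, k))
  out <- .perturbAt(train, idx, spec@kind, cfg,
                    childSeed(spec@seed, "perturb"))
  attr(out, "perturbedIndex") <- sort(idx)
  out
}

#' Enumerate all training-set variants of the protocol
#'
#' The clean baseline plus one variant per (fraction, kind) pair, in
#' deterministic order (kinds outer, fractions inner). With the protocol
#' defaults -- fractions 20, 40, 60, 80, 100 and five kinds -- this yields
#' 26 variants per classifier seed.
#'
#' @param fractions Percentages of training images to perturb.
#' @param kinds Perturbation kinds to enumerate.
#' @param masterSeed Integer seed from which each variant's seed derives.
#' @return List of \linkS4class{TrainVariantSpec} (baseline first).
#' @examples
#' length(enumerateVariants())  # 26
#' @export
enumerateVariants <- function(fractions = c(20, 40, 60, 80, 100),
                              kinds = perturbationKinds(),
                              masterSeed = 1L) {
  if (length(kinds) > 0 && length(fractions) == 0)
    stop("fractions must be nonempty when kinds are given")
  pairs <- if (length(kinds)) expand.grid(fraction = fractions, kind = kinds,
                                          stringsAsFactors = FALSE)
           else data.frame()
  if (nrow(pairs) && anyDuplicated(pairs))
    stop("duplicate (fraction, kind) pairs")
  out <- list(trainVariantSpec(0, "none", seed = masterSeed))
  for (kind in kinds)
    for (f in fractions)
      out[[length(out) + 1L]] <-
        trainVariantSpec(f, kind,
                         seed = childSeed(masterSeed, "variant", kind, f))
  out
}

#' Resample replicated perturbed test sets
#'
#' Yields \code{nReplicates} copies of the test set; in replicate r a fresh
#' uniformly chosen subset of exactly \code{round(fractionPPrime * N /
#' 100)} images is perturbed by the spec's kind. Replicate r is fully
#' determined by (seed, r), so sequences are bitwise reproducible.
#'
#' @param test A nonempty \linkS4class{LabeledImageSet}.
#' @param spec A \linkS4class{TestResampleSpec}.
#' @param cfg A \linkS4class{PerturbationConfig}.
#' @return List of \code{nReplicates} \linkS4class{LabeledImageSet}s.
#' @export
resamplePerturbedTestSets <- function(test, spec,
                                      cfg = perturbationConfig()) {
  if (length(test) == 0L) stop("empty test set")
  N <- length(test)
  k <- roundHalfUp(spec@fractionPPrime * N / 100)
  lapply(seq_len(spec@nReplicates), function(r) {
    if (k == 0L) return(test)
    repSeed <- childSeed(spec@seed, "rep", r)
    idx <- withSeed(childSeed(repSeed, "select"), sample.int(N, k))
    out <- .perturbAt(test, idx, spec@kind, cfg,
                      childSeed(repSeed, "perturb"))
    attr(out, "perturbedIndex") <- sort(idx)
    out
  })
}

#' Build the multi-perturbation training set
#'
#' Partitions a seeded random selection of the training images into five
#' disjoint groups -- one per kind, each of size
#' \code{round(fraction_kind * N)} -- and perturbs each group with its
#' kind. Under the defaults (10% per kind) exactly half of the training
#' images remain untouched.
#'
#' @param train A nonempty \linkS4class{LabeledImageSet}.
#' @param spec A \linkS4class{MultiPerturbSpec}.
#' @param cfg A \linkS4class{PerturbationConfig}.
#' @return A \linkS4class{LabeledImageSet} of the same size.
#' @export
buildMultiperturbedTrainingSet <- function(train, spec = multiPerturbSpec(),
                                           cfg = perturbationConfig()) {
  if (length(train) == 0L) stop("empty training set")
  fr <- spec@trainFractionPerKind[spec@applicationOrder]
  if (sum(fr) > 1 + 1e-12) stop("train fractions sum above 1")
  N <- length(train)
  ks <- roundHalfUp(fr * N)
  if (sum(ks) > N) stop("rounded group sizes exceed the set size")
  if (sum(ks) == 0L) return(train)
  chosen <- withSeed(childSeed(spec@seed, "mselect"),
                     sample.int(N, sum(ks)))
  out <- train
  offset <- 0L
  groups <- list()
  for (kind in spec@applicationOrder) {
    k <- ks[[kind]]
    if (k == 0L) { groups[[kind]] <- integer(); next }
    idx <- chosen[(offset + 1L):(offset + k)]
    offset <- offset + k
    groups[[kind]] <- sort(idx)
    out <- .perturbAt(out, idx, kind, cfg,
                      childSeed(spec@seed, "mtrain", kind))
  }
  attr(out, "perturbedGroups") <- groups
  out
}

#' Build replicated multi-perturbation test sets
#'
#' In every replicate, each image independently receives each perturbation
#' kind with probability \code{testProbabilityPerKind}; selected kinds are
#' applied in the spec's fixed application order (the operators do not
#' commute). An image can thus carry anywhere from 0 to all 5
#' perturbations.
#'
#' @param test A nonempty \linkS4class{LabeledImageSet}.
#' @param spec A \linkS4class{MultiPerturbSpec}.
#' @param cfg A \linkS4class{PerturbationConfig}.
#' @return List of \code{nReplicates} \linkS4class{LabeledImageSet}s.
#' @export
buildMultiperturbedTestSets <- function(test, spec = multiPerturbSpec(),
                                        cfg = perturbationConfig()) {
  if (length(test) == 0L) stop("empty test set")
  N <- length(test)
  p <- spec@testProbabilityPerKind
  lapply(seq_len(spec@nReplicates), function(r) {
    repSeed <- childSeed(spec@seed, "mrep", r)
    apply01 <- withSeed(childSeed(repSeed, "bernoulli"),
      matrix(stats::runif(N * 5) < p, N, 5,
             dimnames = list(NULL, spec@applicationOrder)))
    imgs <- test@images
    for (i in seq_len(N)) {
      for (kind in spec@applicationOrder) {
        if (apply01[i, kind])
          imgs[[i]] <- applyPerturbation(imgs[[i]], kind, cfg,
            seed = childSeed(repSeed, "img", i, kind))
      }
    }
    out <- new("LabeledImageSet", images = imgs, labels = test@labels,
               ids = test@ids, split = test@split)
    attr(out, "kindAssignments") <- apply01
    out
  })
}
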