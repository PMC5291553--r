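# Worked-example parameter triples (D mm^2/s, D* mm^2/s, f fraction) used
# across the fitting tests: pre/mid pairs of two patients, one responder
# and one non-responder.
figure_triples <- list(
  responder_pre     = list(D = 0.906e-3, D_star = 40.4e-3, f = 0.357),
  responder_mid     = list(D = 1.310e-3, D_star = 13.8e-3, f = 0.142),
  non_responder_pre = list(D = 1.110e-3, D_star = 14.8e-3, f = 0.292),
  non_responder_mid = list(D = 1.410e-3, D_star = 27.4e-3, f = 0.214)
)

make_decay <- function(triple, S0 = 1000, scheme = default_scheme()) {
  ivim_decay(ivim_params(triple$D, triple$D_star, triple$f, S0), scheme)
}

# Independent pair-counting AUC: explicit loop over all (case, control)
# pairs, ties scored 1/2. Used as the oracle for the midrank estimator.
brute_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive Youden scan over a dense threshold set (all observed values
# and midpoints, both ends), returning the best J achievable.
brute_best_youden <- function(scores, labels, orientation) {
  s <- sort(unique(scores))
  cand <- sort(unique(c(s, (head(s, -1) + s[-1]) / 2,
                        min(s) - 1, max(s) + 1)))
  best <- -Inf
  for (ct in cand) {
    pred <- if (orientation == "higher") scores >= ct else scores <= ct
    sens <- sum(pred & labels) / sum(labels)
    spec <- sum(!pred & !labels) / sum(!labels)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Exact two-sided Mann-Whitney p by enumerating group assignments and
# counting pairs directly (no midranks), 2*min(tail) convention.
brute_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  u_of <- function(a, b) {
    tot <- 0
    for (p in a) for (q in b) tot <- tot + (p > q) + 0.5 * (p == q)
    tot
  }
  u_obs <- u_of(x, y)
  us <- combn(n, n1, FUN = function(ix) {
    u_of(pooled[ix], pooled[-ix])
  })
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}
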