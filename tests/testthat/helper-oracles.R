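# Independent brute-force oracles. Deliberately naive (explicit loops,
# textbook formulas) and kept free of any package internals so they can
# arbitrate the vectorized implementations.

oracle_dx <- function(values, labels) {
  pos <- values[labels == "driver"]
  neg <- values[labels == "passenger"]
  mp <- sum(pos) / length(pos)
  mn <- sum(neg) / length(neg)
  vp <- sum((pos - mp)^2) / (length(pos) - 1)
  vn <- sum((neg - mn)^2) / (length(neg) - 1)
  (mp - mn)^2 / (vp + vn)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

# plug-in MI by explicit double sum over the contingency table (nats)
oracle_mi <- function(x, y) {
  ux <- sort(unique(x)); uy <- sort(unique(y))
  n <- length(x)
  mi <- 0
  for (a in ux) {
    for (b in uy) {
      pab <- sum(x == a & y == b) / n
      if (pab > 0) {
        mi <- mi + pab * log(pab / ((sum(x == a) / n) * (sum(y == b) / n)))
      }
    }
  }
  mi
}

# all-pairs ROC area, ties counted half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "driver"]
  neg <- scores[labels == "passenger"]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# exhaustive greedy mRMR on a small discretized matrix: at each round score
# every remaining feature from scratch and take the best (first on ties)
oracle_mrmr <- function(d, cls, variant = "MID") {
  n <- ncol(d)
  rel <- sapply(seq_len(n), function(j) oracle_mi(d[, j], cls))
  selected <- integer(0)
  for (round in seq_len(n)) {
    remaining <- setdiff(seq_len(n), selected)
    best <- NA_integer_; best_score <- -Inf
    for (j in remaining) {
      if (length(selected) == 0) {
        score <- rel[j]
      } else {
        red <- mean(sapply(selected, function(s) oracle_mi(d[, j], d[, s])))
        score <- if (variant == "MID") rel[j] - red else rel[j] / max(red, .Machine$double.eps)
      }
      if (score > best_score + 1e-12) {
        best <- j; best_score <- score
      }
    }
    selected <- c(selected, best)
  }
  selected
}
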