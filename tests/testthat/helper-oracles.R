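# Independent brute-force oracles. Each one enumerates exhaustively and is
# kept free of the package's own search/scan code paths.

oracle_confusion <- function(scores, labels, threshold) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(scores)) {
    called_pos <- scores[i] >= threshold
    if (labels[i] == 1 && called_pos) tp <- tp + 1L
    if (labels[i] == 0 && called_pos) fp <- fp + 1L
    if (labels[i] == 0 && !called_pos) tn <- tn + 1L
    if (labels[i] == 1 && !called_pos) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# All (diseased, healthy) pairs, ties 1/2.
oracle_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(s1) * length(s0))
}

oracle_se_sp <- function(scores, labels, t) {
  cc <- oracle_confusion(scores, labels, t)
  c(se = cc$tp / (cc$tp + cc$fn), sp = cc$tn / (cc$tn + cc$fp))
}

# Exhaustive scan over all candidate thresholds for each criterion, with the
# declared tie-breaks (secondary criterion, then smallest threshold).
oracle_threshold <- function(scores, labels, method) {
  cand <- sort(unique(scores))
  best_t <- NA_real_
  best_obj <- -Inf
  best_tie <- -Inf
  for (t in cand) {
    m <- oracle_se_sp(scores, labels, t)
    obj <- switch(method,
      youden    = m["se"] + m["sp"] - 1,
      maxSe     = m["se"],
      maxSp     = m["sp"],
      roc01     = -sqrt((1 - m["se"])^2 + (1 - m["sp"])^2),
      spEqualSe = -abs(m["sp"] - m["se"]),
      minPvalue = {
        cc <- oracle_confusion(scores, labels, t)
        tab <- matrix(c(cc$tn, cc$fn, cc$fp, cc$tp), nrow = 2)
        p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1
             else suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
        -p
      })
    tie <- switch(method, maxSe = m["sp"], maxSp = m["se"], 0)
    if (obj > best_obj + 1e-12 ||
        (abs(obj - best_obj) <= 1e-12 && tie > best_tie + 1e-12)) {
      best_obj <- obj; best_tie <- tie; best_t <- t
    }
  }
  best_t
}

oracle_ui_cells <- function(scores, labels, lower, upper, ix) {
  inside <- scores >= lower & scores <= upper
  list(tn = sum(inside & labels == 0 & scores <= ix),
       fn = sum(inside & labels == 1 & scores <= ix),
       fp = sum(inside & labels == 0 & scores > ix),
       tp = sum(inside & labels == 1 & scores > ix))
}

# Exhaustive search over every (lower, upper) candidate pair.
oracle_ui_search <- function(scores, labels, ix, select = 0.55) {
  s <- sort(unique(scores))
  lows <- s[s <= ix]
  ups <- s[s >= ix]
  best <- NULL
  for (L in lows) for (U in ups) {
    cc <- oracle_ui_cells(scores, labels, L, U, ix)
    if (cc$tp < 1 || cc$fp < 1 || cc$tn < 1 || cc$fn < 1) next
    se <- cc$tp / (cc$tp + cc$fn)
    sp <- cc$tn / (cc$tn + cc$fp)
    if (se > select + 1e-12 || sp > select + 1e-12) next
    cand <- list(lower = L, upper = U,
                 count = cc$tp + cc$fp + cc$tn + cc$fn, width = U - L)
    if (is.null(best) ||
        cand$count > best$count ||
        (cand$count == best$count && cand$width > best$width + 1e-12) ||
        (cand$count == best$count && abs(cand$width - best$width) <= 1e-12 &&
         cand$lower < best$lower)) {
      best <- cand
    }
  }
  best
}

# Exhaustive TG-ROC bound scan: Se(t) = P(pos >= t), Sp(t) = P(neg < t).
oracle_tgroc <- function(scores, labels, level) {
  cand <- sort(unique(scores))
  lower <- upper <- NA_real_
  for (t in cand) {
    se <- mean(scores[labels == 1] >= t)
    if (se >= level) lower <- t          # keep the largest such t
  }
  for (t in rev(cand)) {
    sp <- mean(scores[labels == 0] < t)
    if (sp >= level) upper <- t          # keep the smallest such t
  }
  if (is.na(lower) || is.na(upper)) return(NULL)
  list(lower = min(lower, upper), upper = max(lower, upper),
       reversed = lower > upper)
}

# Small random two-class datasets with limited distinct scores (ties likely).
random_dataset <- function(n = 40, k = 12) {
  scores <- sample(seq(0, 1, length.out = k), n, replace = TRUE)
  labels <- rbinom(n, 1, plogis(4 * (scores - 0.5)))
  if (sum(labels) == 0) labels[which.max(scores)] <- 1
  if (sum(labels) == n) labels[which.min(scores)] <- 0
  labeled_scores(scores, labels)
}
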