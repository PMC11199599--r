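# Independent brute-force oracles used to validate the package's algorithms.
# These deliberately share no code with the implementations: the maxima oracle
# does explicit flood-fill path searches, the Huang oracle evaluates the
# fuzziness measure with naive loops, and the NN oracle is an O(n^2) scan.

neighbours8 <- function(p, nr, nc) {
  r <- (p - 1L) %% nr + 1L
  cl <- (p - 1L) %/% nr + 1L
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    r2 <- r + dr; c2 <- cl + dc
    if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc)
      out <- c(out, (c2 - 1L) * nr + r2)
  }
  out
}

# BFS over `allowed` (logical vector over pixels) from `starts`.
flood_from <- function(starts, allowed, nr, nc) {
  visited <- logical(length(allowed))
  queue <- starts[allowed[starts]]
  visited[queue] <- TRUE
  while (length(queue)) {
    p <- queue[1L]; queue <- queue[-1L]
    for (q in neighbours8(p, nr, nc)) {
      if (allowed[q] && !visited[q]) {
        visited[q] <- TRUE
        queue <- c(queue, q)
      }
    }
  }
  which(visited)
}

# Accepted-maxima oracle: every candidate plateau is tested by brute-force
# path search. Returns a data.frame (row, col, value) of accepted maxima.
oracle_find_maxima <- function(img, mask = NULL, prominence) {
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  maskv <- as.vector(mask)
  # 1. plateaus: connected equal-value components inside the mask
  plat_id <- integer(nr * nc)
  plats <- list()
  for (p in which(maskv)) {
    if (plat_id[p] != 0L) next
    v <- img[p]
    members <- flood_from(p, maskv & as.vector(img == v), nr, nc)
    plats[[length(plats) + 1L]] <- members
    plat_id[members] <- length(plats)
  }
  # 2. candidates: plateaus with no strictly higher masked neighbour
  is_cand <- vapply(plats, function(m) {
    for (p in m) for (q in neighbours8(p, nr, nc))
      if (maskv[q] && img[q] > img[p]) return(FALSE)
    TRUE
  }, logical(1))
  cand <- which(is_cand)
  if (!length(cand)) return(data.frame(row = numeric(0), col = numeric(0),
                                       value = numeric(0)))
  vals <- vapply(cand, function(i) img[plats[[i]][1L]], numeric(1))
  anchors <- vapply(cand, function(i) min(plats[[i]]), integer(1))
  ord <- order(-vals, anchors)
  cand <- cand[ord]; vals <- vals[ord]; anchors <- anchors[ord]
  # 3. connected mask regions (top candidate per region always reported
  #    unless the region is constant-valued)
  region <- integer(nr * nc)
  nreg <- 0L
  for (p in which(maskv)) {
    if (region[p] != 0L) next
    nreg <- nreg + 1L
    region[flood_from(p, maskv, nr, nc)] <- nreg
  }
  region_const <- vapply(seq_len(nreg), function(g) {
    px <- which(region == g)
    length(unique(img[px])) == 1L
  }, logical(1))
  seen_region <- logical(nreg)
  rank_of_plat <- integer(length(plats))
  rank_of_plat[cand] <- seq_along(cand)
  accepted <- logical(length(cand))
  for (k in seq_along(cand)) {
    members <- plats[[cand[k]]]
    g <- region[members[1L]]
    v <- vals[k]
    if (!seen_region[g]) {
      seen_region[g] <- TRUE
      accepted[k] <- !region_const[g]
      next
    }
    reach <- flood_from(members, maskv & as.vector(img >= v - prominence),
                        nr, nc)
    higher <- any(img[reach] > v)
    earlier_equal <- FALSE
    if (!higher) {
      eq <- reach[img[reach] == v]
      pl <- unique(plat_id[eq])
      pl <- pl[pl != cand[k]]
      earlier_equal <- any(rank_of_plat[pl] > 0L & rank_of_plat[pl] < k)
    }
    accepted[k] <- !higher && !earlier_equal
  }
  idx <- which(accepted)
  data.frame(
    row = vapply(idx, function(k) mean((plats[[cand[k]]] - 1L) %% nr + 1L),
                 numeric(1)),
    col = vapply(idx, function(k) mean((plats[[cand[k]]] - 1L) %/% nr + 1L),
                 numeric(1)),
    value = vals[idx])
}

# Canonical ordering for comparing maxima sets.
maxima_key <- function(df) {
  df <- df[order(round(df$row, 6), round(df$col, 6)), , drop = FALSE]
  sprintf("%.6f,%.6f,%.9g", df$row, df$col, df$value)
}

# Naive Huang fuzziness minimization (same tie rule: midpoint of the tied
# run), computed with per-level loops.
oracle_huang <- function(counts, levels = seq_along(counts) - 1) {
  occ <- which(counts > 0)
  first <- occ[1L]; last <- occ[length(occ)]
  C <- levels[last] - levels[first]
  ent <- function(u) {
    if (u >= 1) return(0)
    -u * log(u) - (1 - u) * log(1 - u)
  }
  cand <- first:(last - 1L)
  S <- numeric(length(cand))
  for (ci in seq_along(cand)) {
    k <- cand[ci]
    n0 <- sum(counts[1:k]); n1 <- sum(counts[(k + 1):length(counts)])
    mu0 <- sum(counts[1:k] * levels[1:k]) / n0
    mu1 <- sum(counts[(k + 1):length(counts)] *
                 levels[(k + 1):length(counts)]) / n1
    s <- 0
    for (g in seq_along(counts)) {
      if (counts[g] == 0) next
      mu <- if (g <= k) mu0 else mu1
      u <- 1 / (1 + abs(levels[g] - mu) / C)
      s <- s + counts[g] * ent(u)
    }
    S[ci] <- s
  }
  tied <- which(S - min(S) <= 1e-10 * max(1, abs(min(S))))
  levels[cand[tied[ceiling(length(tied) / 2)]]]
}

# O(n^2) all-pairs nearest-neighbour oracle (per nucleus, ties to the first
# comparator focus).
oracle_nn <- function(foci_a, foci_b) {
  n <- nrow(foci_a)
  d <- rep(NA_real_, n)
  idx <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    best <- Inf; bj <- NA_integer_
    for (j in seq_len(nrow(foci_b))) {
      if (foci_b$nucleus_id[j] != foci_a$nucleus_id[i]) next
      dij <- sqrt((foci_a$row[i] - foci_b$row[j])^2 +
                  (foci_a$col[i] - foci_b$col[j])^2)
      if (dij < best) { best <- dij; bj <- j }
    }
    if (is.finite(best)) { d[i] <- best; idx[i] <- bj }
  }
  list(distance = d, index = idx)
}

# Jaccard overlap between one truth mask and its best-matching label.
best_jaccard <- function(truth_mask, labels) {
  ids <- setdiff(unique(labels[truth_mask]), 0L)
  if (!length(ids)) return(0)
  max(vapply(ids, function(id) {
    m <- labels == id
    sum(m & truth_mask) / sum(m | truth_mask)
  }, numeric(1)))
}
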