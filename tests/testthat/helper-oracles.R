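# Independent brute-force oracles used across the suite. These are
# deliberately naive (loops, full enumeration) and share no machinery
# with the package implementations they check.

rdna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

rc_chars <- function(x) rev(chartr("ACGTN", "TGCAN", x))

# exhaustive transition search: maximize a + b over all splits where the
# junction prefix of length a equals the flank prefix and the suffix of
# length b equals the flank suffix; overlap = a + b - n (mh), deficit =
# insertion
oracle_dissect <- function(junction, prox, dist) {
  n <- nchar(junction)
  nd <- nchar(dist)
  # every candidate prefix/suffix length is tested by substring equality
  a_ok <- vapply(seq_len(min(n, nchar(prox))), function(a)
    substr(junction, 1L, a) == substr(prox, 1L, a), logical(1))
  b_ok <- vapply(seq_len(min(n, nd)), function(b)
    substr(junction, n - b + 1L, n) == substr(dist, nd - b + 1L, nd),
    logical(1))
  a <- if (any(a_ok)) max(which(a_ok)) else 0L
  b <- if (any(b_ok)) max(which(b_ok)) else 0L
  if (a + b >= n) {
    list(mh_len = a + b - n,
         mh_seq = if (a + b > n) substr(junction, n - b + 1L, a) else "",
         insertion = NULL)
  } else {
    list(mh_len = 0L, mh_seq = "",
         insertion = substr(junction, a + 1L, n - b))
  }
}

# run-based naive direct-repeat scan (while-loops, no vectorization)
oracle_direct <- function(seq, min_arm = 10L, max_arm = 150L,
                          max_spacer = 9L, mask_run = 8L) {
  x <- strsplit(seq, "")[[1]]
  r <- rle(x); long <- r$values %in% c("A", "C", "G", "T") &
    r$lengths >= mask_run
  if (any(long)) { r$values[long] <- "N"; x <- inverse.rle(r) }
  n <- length(x)
  out <- list()
  for (d in min_arm:min(n - 1L, max_arm + max_spacer)) {
    i <- 1L
    while (i <= n - d) {
      if (x[i] != "N" && x[i] == x[i + d]) {
        len <- 0L
        while (i + len <= n - d && x[i + len] != "N" &&
               x[i + len] == x[i + len + d]) len <- len + 1L
        arm <- min(len, max_arm, d)
        spacer <- d - arm
        if (arm >= min_arm && spacer >= 0L && spacer <= max_spacer) {
          out[[length(out) + 1L]] <- c(i, i + d, arm, spacer)
        }
        i <- i + len
      } else i <- i + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(start1 = integer(0), start2 = integer(0),
                      arm_len = integer(0), spacer = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(start1 = m[, 1], start2 = m[, 2], arm_len = m[, 3],
             spacer = m[, 4])
}

# run-based naive inverted-repeat scan along anti-diagonals
oracle_inverted <- function(seq, min_arm = 6L, max_arm = 150L,
                            max_spacer = 99L, mask_run = 8L) {
  x <- strsplit(seq, "")[[1]]
  r <- rle(x); long <- r$values %in% c("A", "C", "G", "T") &
    r$lengths >= mask_run
  if (any(long)) { r$values[long] <- "N"; x <- inverse.rle(r) }
  cx <- chartr("ACGTN", "TGCAN", x)
  n <- length(x)
  out <- list()
  for (s in (2L * min_arm + 1L):(2L * n - 1L)) {
    p_max <- min((s - 1L) %/% 2L, n - 1L)
    p_min <- max(1L, s - n)
    if (p_max < p_min) next
    p <- p_min
    while (p <= p_max) {
      if (x[p] != "N" && x[p] == cx[s - p]) {
        len <- 0L
        while (p + len <= p_max && x[p + len] != "N" &&
               x[p + len] == cx[s - p - len]) len <- len + 1L
        p2 <- p + len - 1L
        spacer <- s - 2L * p2 - 1L
        arm <- min(len, max_arm)
        if (spacer <= max_spacer && arm >= min_arm) {
          out[[length(out) + 1L]] <- c(p2 - arm + 1L, s - p2, arm, spacer)
        }
        p <- p + len
      } else p <- p + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(start1 = integer(0), start2 = integer(0),
                      arm_len = integer(0), spacer = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(start1 = m[, 1], start2 = m[, 2], arm_len = m[, 3],
             spacer = m[, 4])
}

# full-enumeration Fisher two-tailed p for fixed margins, no dhyper:
# probabilities from binomial coefficients directly
oracle_fisher_p <- function(a, b, c_, d) {
  r <- a + b; s <- c_ + d; m <- a + c_; N <- r + s
  if (r == 0 || s == 0 || m == 0 || m == N) return(1)
  support <- max(0, m - s):min(r, m)
  probs <- vapply(support, function(k) {
    exp(lchoose(r, k) + lchoose(s, m - k) - lchoose(N, m))
  }, numeric(1))
  p_obs <- probs[match(a, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exhaustive k-subset minimal inclusive span
oracle_min_span <- function(coords, k) {
  combs <- utils::combn(sort(coords), k)
  spans <- apply(combs, 2L, function(v) max(v) - min(v) + 1)
  min(spans)
}

# naive O(n*m) interval overlap
oracle_overlap <- function(queries, features) {
  vapply(seq_len(nrow(queries)), function(i) {
    any(features$contig == queries$contig[i] &
          features$start <= queries$end[i] &
          features$end >= queries$start[i])
  }, logical(1))
}

# affine-gap Needleman-Wunsch score; gap of length L costs open + L * ext
oracle_nw_affine <- function(a, b, match = 1, mismatch = -1,
                             open = 2, ext = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)   # gap in b (consume a)
  Iy <- matrix(NEG, n + 1, m + 1)   # gap in a (consume b)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -open - (i - 1) * ext
  for (j in 2:(m + 1)) Iy[1, j] <- -open - (j - 1) * ext
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                     Iy[i - 1, j - 1]) + sub
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# plant a microhomology junction; returns junction/flanks/planted mh
make_mh_junction <- function(flank_len = 80L, mh = 2L) {
  repeat {
    P <- rdna(flank_len)
    Dtail <- rdna(flank_len - mh)
    D <- paste0(substr(P, flank_len - mh + 1L, flank_len), Dtail)
    junction <- paste0(P, substr(D, mh + 1L, flank_len))
    o <- oracle_dissect(junction, P, D)
    if (o$mh_len == mh && is.null(o$insertion)) {
      return(list(junction = junction, prox = P, dist = D, mh = mh))
    }
  }
}
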