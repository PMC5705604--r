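# Shared fixtures: small trio configurations and an independent brute-force
# Needleman-Wunsch oracle (match +1, mismatch -1, gap -1, tie preference
# diagonal > up > left), kept separate from the package implementation.

tiny_config <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_chromosomes = 4, chrom_length = 2.5e5,
                   array_length_range = c(12000, 16000),
                   meth_domain_length = 2500,
                   n_insertions = 2, n_deletions = 2, tss_count = 6,
                   n_contigs = 24)
  args <- utils::modifyList(defaults, list(...))
  do.call(trio_config, args)
}

# memoize expensive trios within one test run
.trio_cache <- new.env(parent = emptyenv())
cached_trio <- function(key, cfg) {
  if (is.null(.trio_cache[[key]])) .trio_cache[[key]] <- generate_trio(cfg)
  .trio_cache[[key]]
}

oracle_nw <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  P <- matrix(0L, n + 1, m + 1)  # 0 diag, 1 up, 2 left
  S[1, ] <- -(0:m); S[, 1] <- -(0:n)
  P[1, ] <- 2L; P[, 1] <- 1L
  ok <- function(x, y) x == y && x %in% c("A", "C", "G", "T")
  for (i in 1:n) for (j in 1:m) {
    sd <- S[i, j] + if (ok(av[i], bv[j])) 1 else -1
    su <- S[i, j + 1] - 1
    sl <- S[i + 1, j] - 1
    best <- sd; p <- 0L
    if (su > best) { best <- su; p <- 1L }
    if (sl > best) { best <- sl; p <- 2L }
    S[i + 1, j + 1] <- best; P[i + 1, j + 1] <- p
  }
  i <- n; j <- m; matches <- 0
  while (i > 0 || j > 0) {
    p <- P[i + 1, j + 1]
    if (i > 0 && j > 0 && p == 0L) {
      if (ok(av[i], bv[j])) matches <- matches + 1
      i <- i - 1; j <- j - 1
    } else if (i > 0 && (p == 1L || j == 0)) i <- i - 1
    else j <- j - 1
  }
  list(score = S[n + 1, m + 1], matches = matches)
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# naive UPGMA recomputation used as an oracle (average linkage, heights as
# half the merge distance), independent of the package implementation
oracle_upgma_heights <- function(d) {
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(merge = hc$merge, height = hc$height / 2)
}

# naive Ward (ward.D2 convention) agglomeration via the Lance-Williams
# update on squared distances
oracle_ward <- function(d) {
  n <- nrow(d)
  D2 <- d^2
  sizes <- rep(1, n)
  active <- 1:n
  id <- -(1:n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (s in 1:(n - 1)) {
    m <- length(active); best <- NULL; bd <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      v <- D2[active[i], active[j]]
      if (v < bd - 1e-15) { bd <- v; best <- c(i, j) }
    }
    ai <- active[best[1]]; aj <- active[best[2]]
    v <- c(id[ai], id[aj])
    merge[s, ] <- v[order(v >= 0, abs(v))]  # hclust row convention
    height[s] <- sqrt(bd)
    for (kk in active) {
      if (kk %in% c(ai, aj)) next
      na <- sizes[ai]; nb <- sizes[aj]; nk <- sizes[kk]
      v <- ((na + nk) * D2[ai, kk] + (nb + nk) * D2[aj, kk] -
              nk * D2[ai, aj]) / (na + nb + nk)
      D2[ai, kk] <- D2[kk, ai] <- v
    }
    sizes[ai] <- sizes[ai] + sizes[aj]
    id[ai] <- s
    active <- active[active != aj]
  }
  list(merge = merge, height = height)
}

# exhaustive best colinear chain (strict non-overlap, same gap penalty)
oracle_best_chain_score <- function(al, gap_rate = 0.01, cap = NULL) {
  if (is.null(cap)) cap <- stats::median(al$score)
  n <- nrow(al)
  best <- 0
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    sub <- al[idx, , drop = FALSE]
    sub <- sub[order(sub$qstart), , drop = FALSE]
    okc <- TRUE
    total <- sum(sub$score)
    if (nrow(sub) > 1) {
      for (i in 2:nrow(sub)) {
        gq <- sub$qstart[i] - sub$qend[i - 1] - 1
        gt <- sub$tstart[i] - sub$tend[i - 1] - 1
        if (gq < 0 || gt < 0) { okc <- FALSE; break }
        total <- total - min(gap_rate * (gq + gt), cap)
      }
    }
    if (okc && total > best) best <- total
  }
  best
}

rand_chain_instance <- function(n) {
  # strictly disjoint query and target intervals (spacing exceeds the widest
  # member) in shuffled target order, so the brute-force subset oracle and
  # the DP share the same admissibility rule
  qs <- cumsum(sample(150:300, n, TRUE))
  qe <- qs + sample(30:100, n, TRUE)
  ord <- sample(n)
  ts <- cumsum(sample(150:300, n, TRUE))[ord]
  te <- ts + sample(30:100, n, TRUE)
  data.frame(qstart = qs, qend = qe, tstart = ts, tend = te,
             strand = "+", score = sample(10:100, n, TRUE))
}

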