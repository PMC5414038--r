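# Independent brute-force oracles shared by unit and acceptance tests.
# These deliberately avoid the code paths they verify.

# complete-linkage agglomeration implemented directly: start from
# singletons, repeatedly merge the pair of clusters with the smallest
# maximum inter-point distance, stop at k clusters
oracle_complete_linkage <- function(D, k) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lab <- integer(n)
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}

# same partition up to label renaming: co-membership matrices must agree
same_partition <- function(a, b) {
  all(outer(a, a, `==`) == outer(b, b, `==`))
}

# strand-aware genomic context by exhaustive per-transcript interval scan
oracle_context <- function(cpgs, transcripts, up = 1500L) {
  vapply(seq_len(nrow(cpgs)), function(i) {
    ch <- cpgs$chrom[i]; pos <- cpgs$pos[i]
    tss <- FALSE; genic <- FALSE
    for (t in seq_len(nrow(transcripts))) {
      if (transcripts$chrom[t] != ch) next
      s <- transcripts$start[t]; e <- transcripts$end[t]
      if (transcripts$strand[t] == "+") {
        if (pos >= s - up && pos <= s - 1) tss <- TRUE
      } else {
        if (pos >= e + 1 && pos <= e + up) tss <- TRUE
      }
      if (pos >= s && pos <= e) genic <- TRUE
    }
    if (tss) "TSS" else if (genic) "Genic" else "Intergenic"
  }, character(1))
}

# hypergeometric upper tail by direct summation
oracle_hyper_upper <- function(x, m, n, kdraw) {
  sum(vapply(x:min(kdraw, m), dhyper, numeric(1), m = m, n = n, k = kdraw))
}

# Wallenius pmf by exhaustive recursion over weighted sequential draws
# (two weight classes: n_set items with weight w, n_other with weight 1)
oracle_wallenius_pmf <- function(n_set, n_other, n_draws, w) {
  probs <- numeric(n_draws + 1L)
  recur <- function(s_rem, o_rem, left, s_drawn, pr) {
    if (left == 0L) {
      probs[s_drawn + 1L] <<- probs[s_drawn + 1L] + pr
      return(invisible())
    }
    tot <- w * s_rem + o_rem
    if (s_rem > 0L)
      recur(s_rem - 1L, o_rem, left - 1L, s_drawn + 1L, pr * w * s_rem / tot)
    if (o_rem > 0L)
      recur(s_rem, o_rem - 1L, left - 1L, s_drawn, pr * o_rem / tot)
  }
  recur(n_set, n_other, n_draws, 0L, 1)
  probs
}
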