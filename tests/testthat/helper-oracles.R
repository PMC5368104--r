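# Independent oracles, deliberately naive.

# all permutations of 1..n (n <= 8)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  smaller <- all_perms(n - 1L)
  out <- vector("list", n)
  for (pos in seq_len(n)) {
    block <- cbind(smaller, n, deparse.level = 0L)
    if (pos < n) {
      block <- block[, c(seq_len(pos - 1L), n, pos:(n - 1L)), drop = FALSE]
    }
    out[[pos]] <- block
  }
  do.call(rbind, out)
}

# mean rank of `correct` over every tie-breaking order consistent with the
# scores: enumerate all permutations, keep score-sorted ones, average the
# position of the correct candidate
perm_rank_oracle <- function(scores, correct) {
  n <- length(scores)
  perms <- all_perms(n)
  valid <- apply(perms, 1L, function(p) !is.unsorted(-scores[p]))
  positions <- apply(perms[valid, , drop = FALSE], 1L, function(p) {
    which(p == correct)
  })
  mean(positions)
}

# brute-force group-by-max stereo collapse
collapse_oracle <- function(skeleton, score) {
  agg <- tapply(score, skeleton, max)
  tibble::tibble(skeleton = names(agg), score = as.numeric(agg))
}

# exhaustive optimal one-to-one peak matching (maximum total product)
cosine_oracle <- function(a, b, tol_ppm = 10, scaling = "sqrt") {
  ua <- if (scaling == "sqrt") sqrt(a$intensity) else a$intensity
  ub <- if (scaling == "sqrt") sqrt(b$intensity) else b$intensity
  na <- length(a$mz)
  eligible <- lapply(seq_len(na), function(i) {
    which(abs(a$mz[i] - b$mz) <= (a$mz[i] + b$mz) / 2 * tol_ppm * 1e-6)
  })
  best <- function(i, used) {
    if (i > na) return(0)
    top <- best(i + 1L, used) # leave peak i unmatched
    for (j in setdiff(eligible[[i]], used)) {
      top <- max(top, ua[i] * ub[j] + best(i + 1L, c(used, j)))
    }
    top
  }
  min(1, best(1L, integer()) / (sqrt(sum(ua^2)) * sqrt(sum(ub^2))))
}

# naive per-entry recount of the statistic panel
recount_oracle <- function(avg_ranks) {
  rounded <- ceiling(avg_ranks)
  ok <- !is.na(avg_ranks)
  list(
    top1 = sum(rounded[ok] == 1),
    top3 = sum(rounded[ok] <= 3),
    top10 = sum(rounded[ok] <= 10),
    mean_rank = mean(avg_ranks[ok]),
    median_rank = median(avg_ranks[ok]),
    formula1 = sum(c(25, 18, 15, 12, 10, 8, 6, 4, 2, 1)[rounded[ok][rounded[ok] <= 10]]),
    medal_score = sum(c(5, 3, 1)[rounded[ok][rounded[ok] <= 3]])
  )
}
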