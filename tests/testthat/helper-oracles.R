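# Shared fixtures and independent brute-force oracles for the test suite.
# Oracles here deliberately avoid the package's own code paths.

# small atlas with two regions and mixed gene classes
toy_atlas <- function() {
  m <- matrix(
    c(1, 2, 3, 4, 5,
      0, 1, 0, 2, 0,
      5, 5, 5, 5, 5),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("gA", "gB", "gC"),
                    c("v1", "v2", "v3", "v4", "v5"))
  )
  lookup <- data.frame(
    voxel_id = c("v1", "v2", "v3", "v4", "v5"),
    x = c(0L, 1L, 2L, 0L, 1L),
    y = c(0L, 0L, 0L, 1L, 1L),
    z = 0L,
    region_label = c("OB", "OB", "OB", "CTX", "CTX"),
    stringsAsFactors = FALSE
  )
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    symbol = c("GeneA", "GeneB", "GeneC"),
    gene_class = c("ion_channel", "ion_channel", "other"),
    stringsAsFactors = FALSE
  )
  expression_atlas(m, lookup, genes = genes)
}

# connectivity of a logical 3D mask on the 6-neighbour grid, by repeated
# pairwise adjacency sweeps (quadratic, independent of any flood fill)
bf_connected6 <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) <= 1L) return(nrow(idx) == 1L)
  in_comp <- c(TRUE, rep(FALSE, nrow(idx) - 1L))
  repeat {
    grew <- FALSE
    for (i in which(!in_comp)) {
      for (j in which(in_comp)) {
        if (sum(abs(idx[i, ] - idx[j, ])) == 1L) {
          in_comp[i] <- TRUE
          grew <- TRUE
          break
        }
      }
    }
    if (!grew) break
  }
  all(in_comp)
}

# type-7 25th percentile written out long-hand, then >= retention
bf_quartile_retained <- function(r) {
  x <- sort(r)
  n <- length(x)
  h <- (n - 1) * 0.25
  lo <- floor(h) + 1
  cutoff <- x[lo] + (h - lo + 1) * (if (lo < n) x[lo + 1] - x[lo] else 0)
  r >= cutoff
}

# all permutations of 1..n as a list (recursive, independent implementation)
bf_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in bf_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# best-permutation accuracy by direct enumeration
bf_accuracy <- function(cluster, truth, s) {
  best <- 0
  for (p in bf_perms(s)) {
    acc <- mean(unlist(p)[cluster] == truth)
    if (acc > best) best <- acc
  }
  best
}

# does a column ordering satisfy the peak-sort rule?
bf_valid_peak_order <- function(H, ord) {
  peak_row <- apply(H, 2, which.max)
  peak_val <- apply(H, 2, max)
  pr <- peak_row[ord]
  pv <- peak_val[ord]
  if (is.unsorted(pr)) return(FALSE)
  for (k in unique(pr)) {
    v <- pv[pr == k]
    if (is.unsorted(rev(v))) return(FALSE)
  }
  TRUE
}

# first-merge pair of single/complete linkage: the closest column pair
bf_first_merge <- function(W) {
  s <- ncol(W)
  best <- c(NA, NA)
  bestd <- Inf
  for (i in 1:(s - 1)) {
    for (j in (i + 1):s) {
      d <- sqrt(sum((W[, i] - W[, j])^2))
      if (d < bestd) {
        bestd <- d
        best <- c(i, j)
      }
    }
  }
  list(pair = best, height = bestd)
}
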