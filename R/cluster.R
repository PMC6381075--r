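#' @name cluster_stats
#' @title Cluster-based permutation statistics over channel-frequency-time
#'   triplets
#' @description
#' Nonparametric control of the multiple-comparisons problem for paired
#' condition contrasts of time-frequency data. A dependent-samples t-value is
#' computed at every (channel, frequency, time) triplet; contiguous
#' same-signed triplets exceeding the two-sided `alpha_triplet` threshold
#' (two or more of them) form clusters whose mass is the sum of their
#' t-values; the observed cluster masses are referred to a Monte Carlo null
#' distribution of the maximum cluster mass obtained by randomly exchanging
#' the two condition means within each subject (equivalently, flipping the
#' sign of each subject's difference map). A cluster is significant when its
#' (optionally Bonferroni-corrected) Monte Carlo p falls at or below
#' `tail_alpha` on its tail.
#'
#' Contiguity combines the channel adjacency graph (template 10-20 positions)
#' with +/- one grid bin in frequency and in time; diagonal moves are not
#' contiguous. Triplets with a missing value in any subject (e.g. bins
#' shifted out of support by ICF alignment) are excluded.
NULL

# --- internal machinery ----------------------------------------------------

# Stack per-subject (ch x f x t) arrays into an n x p matrix (column-major
# flattening: channel fastest, then frequency, then time).
stack_subjects <- function(lst) {
  n <- length(lst)
  p <- length(lst[[1]])
  out <- matrix(NA_real_, n, p)
  for (s in seq_len(n)) out[s, ] <- as.vector(lst[[s]])
  out
}

# Align an adjacency matrix to the channel set of the analysed arrays
# (subset by name; missing channels get no neighbours).
match_adjacency <- function(adjacency, channels) {
  if (is.null(adjacency)) return(channel_adjacency(channels))
  ix <- match(channels, rownames(adjacency))
  if (anyNA(ix))
    stop("adjacency lacks channel(s): ",
         paste(channels[is.na(ix)], collapse = ", "))
  out <- unclass(adjacency)[ix, ix, drop = FALSE]
  class(out) <- c("wm_adjacency", class(out))
  out
}

# Neighbour lists over the flattened triplet grid, restricted to `valid`
# columns and re-indexed into valid space.
triplet_neighbors <- function(dims, adjacency, valid) {
  C <- dims[1]; F <- dims[2]; T <- dims[3]
  ch_nb <- lapply(seq_len(C), function(c) which(adjacency[c, ]))
  vmap <- integer(C * F * T)
  vmap[valid] <- seq_len(sum(valid))
  nbrs <- vector("list", sum(valid))
  k <- 0L
  for (t in seq_len(T)) for (f in seq_len(F)) for (c in seq_len(C)) {
    i <- c + (f - 1L) * C + (t - 1L) * C * F
    if (!valid[i]) next
    k <- k + 1L
    nb <- integer(0)
    if (length(ch_nb[[c]]))
      nb <- ch_nb[[c]] + (f - 1L) * C + (t - 1L) * C * F
    if (f > 1L) nb <- c(nb, i - C)
    if (f < F)  nb <- c(nb, i + C)
    if (t > 1L) nb <- c(nb, i - C * F)
    if (t < T)  nb <- c(nb, i + C * F)
    nb <- nb[valid[nb]]
    nbrs[[k]] <- vmap[nb]
  }
  nbrs
}

# Connected components (>= min_size members) of `members` under `nbrs`.
find_components <- function(members, nbrs, n_valid, min_size = 2L) {
  if (!length(members)) return(list())
  inmask <- logical(n_valid); inmask[members] <- TRUE
  seen <- logical(n_valid)
  comps <- list()
  for (s in members) {
    if (seen[s]) next
    seen[s] <- TRUE
    stack <- s
    comp <- integer(0)
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      comp <- c(comp, v)
      nb <- nbrs[[v]]
      nb <- nb[inmask[nb] & !seen[nb]]
      if (length(nb)) {
        seen[nb] <- TRUE
        stack <- c(stack, nb)
      }
    }
    if (length(comp) >= min_size) comps[[length(comps) + 1L]] <- comp
  }
  comps
}

# Max positive / min negative cluster mass of a t-vector (0 when none).
extreme_masses <- function(tv, tcrit, nbrs, n_valid) {
  pos <- find_components(which(tv >= tcrit), nbrs, n_valid)
  neg <- find_components(which(tv <= -tcrit), nbrs, n_valid)
  c(if (length(pos)) max(vapply(pos, function(i) sum(tv[i]), 0)) else 0,
    if (length(neg)) min(vapply(neg, function(i) sum(tv[i]), 0)) else 0)
}

# Vectorised paired t for a block of sign patterns: S is B x n in {-1, 1}.
t_block <- function(S, D, ss) {
  n <- ncol(S)
  M <- (S %*% D) / n
  V <- sweep(-n * M^2, 2, ss, `+`) / (n - 1)
  Tm <- M / sqrt(V / n)
  Tm[!is.finite(Tm)] <- 0
  Tm
}

# --- exported surface ------------------------------------------------------

#' Dependent-samples t-map over channel-frequency-time triplets
#'
#' @param cond_a,cond_b lists of per-subject condition-mean arrays
#'   (channels x freqs x times, as from [tfr_mean()]), paired by position.
#' @return A `wm_tmap`: list with `t` (array, `NA` at excluded triplets),
#'   `df`, and the axes taken from the arrays' dimnames.
#' @export
triplet_t_map <- function(cond_a, cond_b) {
  n <- length(cond_a)
  if (n < 2 || length(cond_b) != n)
    stop("need >= 2 subjects, paired across conditions")
  dims <- dim(cond_a[[1]])
  if (!all(vapply(c(cond_a, cond_b), function(x) identical(dim(x), dims), TRUE)))
    stop("all subject arrays must share identical axes")
  D <- stack_subjects(cond_a) - stack_subjects(cond_b)
  valid <- apply(is.finite(D), 2, all)
  m <- colMeans(D)
  ss <- colSums(D^2)
  v <- (ss - n * m^2) / (n - 1)
  tv <- m / sqrt(v / n)
  zerovar <- valid & (v <= 0 | !is.finite(tv))
  if (any(zerovar)) {
    warning(sum(zerovar), " triplet(s) with zero difference variance; t set to 0")
    tv[zerovar] <- 0
  }
  tv[!valid] <- NA_real_
  tarr <- array(tv, dims, dimnames = dimnames(cond_a[[1]]))
  out <- list(t = tarr, df = n - 1L)
  class(out) <- "wm_tmap"
  out
}

#' Form supra-threshold clusters from a t-map
#'
#' Connected components of same-signed triplets with `p < alpha_triplet`
#' (two-sided) under the combined channel/frequency/time adjacency; clusters
#' need at least two triplets; mass is the sum of member t-values.
#'
#' @param tmap a `wm_tmap` from [triplet_t_map()].
#' @param adjacency channel adjacency matrix from [channel_adjacency()]
#'   (default: built from the t-map's channel names).
#' @param alpha_triplet two-sided triplet threshold (default 0.05).
#' @return List of clusters, each a list with `triplets` (data.frame
#'   `channel`, `freq`, `time`, `t`), `mass` and `sign`; ordered by
#'   decreasing |mass|.
#' @export
form_clusters <- function(tmap, adjacency = NULL, alpha_triplet = 0.05) {
  stopifnot(inherits(tmap, "wm_tmap"))
  dims <- dim(tmap$t)
  dn <- dimnames(tmap$t)
  adjacency <- match_adjacency(adjacency, dn[[1]])
  tcrit <- qt(1 - alpha_triplet / 2, tmap$df)
  tv_full <- as.vector(tmap$t)
  valid <- is.finite(tv_full)
  nbrs <- triplet_neighbors(dims, adjacency, valid)
  tv <- tv_full[valid]
  vidx <- which(valid)
  n_valid <- length(tv)
  comps <- c(lapply(find_components(which(tv >= tcrit), nbrs, n_valid), identity),
             lapply(find_components(which(tv <= -tcrit), nbrs, n_valid), identity))
  clusters <- lapply(comps, function(ci) {
    full <- vidx[ci]
    c0 <- (full - 1L) %% dims[1] + 1L
    f0 <- ((full - 1L) %/% dims[1]) %% dims[2] + 1L
    t0 <- (full - 1L) %/% (dims[1] * dims[2]) + 1L
    trip <- data.frame(channel = dn[[1]][c0],
                       freq = as.numeric(dn[[2]][f0]),
                       time = as.numeric(dn[[3]][t0]),
                       t = tv[ci], stringsAsFactors = FALSE)
    list(triplets = trip, mass = sum(tv[ci]), sign = sign(sum(tv[ci])))
  })
  ord <- order(-abs(vapply(clusters, `[[`, 0, "mass")))
  clusters[ord]
}

#' Cluster-based permutation contrast of two paired conditions
#'
#' See the module description under [cluster_stats]. The null distribution
#' exchanges the two condition means within each subject (a sign flip of the
#' paired difference map), recomputes the t-map and the clusters, and records
#' the maximum positive and minimum negative cluster mass per permutation.
#' Monte Carlo p-values use the +1 correction,
#' `p = (1 + #extreme) / (1 + n_perm)`. With `exact = TRUE` (n <= 16
#' subjects) all `2^n` sign patterns are enumerated instead and
#' `p = #extreme / 2^n` (the identity pattern is in the set).
#'
#' @inheritParams triplet_t_map
#' @param adjacency channel adjacency matrix (default from channel names).
#' @param alpha_triplet two-sided triplet-level threshold (default 0.05).
#' @param n_perm number of Monte Carlo permutations (default 30000).
#' @param tail_alpha per-tail significance threshold on the corrected p
#'   (default 0.025).
#' @param bonferroni multiplicity factor applied to the Monte Carlo p
#'   (default 1; 2 for the merged-condition analyses).
#' @param seed permutation RNG seed (recorded in the result).
#' @param exact enumerate all sign patterns instead of sampling.
#' @return A `wm_cluster_result`: `clusters` (each with `triplets`, `mass`,
#'   `sign`, `p`, `p_corrected`, `significant`), the observed `tmap`,
#'   `null_max` / `null_min` distributions, `n_perm`, `seed`, `bonferroni`,
#'   `tail_alpha`, `alpha_triplet`, `exact`.
#' @export
permutation_test <- function(cond_a, cond_b, adjacency = NULL,
                             alpha_triplet = 0.05, n_perm = 30000,
                             tail_alpha = 0.025, bonferroni = 1,
                             seed = 1, exact = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  tmap <- triplet_t_map(cond_a, cond_b)
  n <- length(cond_a)
  dims <- dim(tmap$t)
  dn <- dimnames(tmap$t)
  adjacency <- match_adjacency(adjacency, dn[[1]])
  clusters <- suppressWarnings(form_clusters(tmap, adjacency, alpha_triplet))

  D <- stack_subjects(cond_a) - stack_subjects(cond_b)
  valid <- apply(is.finite(D), 2, all)
  Dv <- D[, valid, drop = FALSE]
  ss <- colSums(Dv^2)
  tcrit <- qt(1 - alpha_triplet / 2, tmap$df)
  nbrs <- triplet_neighbors(dims, adjacency, valid)
  n_valid <- sum(valid)

  if (exact) {
    if (n > 16) stop("exact enumeration limited to <= 16 subjects")
    B <- 2L^n
    signs_of <- function(ix) {
      # ix in 0..(B-1) mapped to a {-1, 1}^n row
      m <- matrix(0L, length(ix), n)
      for (b in seq_len(n)) m[, b] <- bitwAnd(ix %/% 2L^(b - 1L), 1L)
      2L * m - 1L
    }
    chunks <- split(0:(B - 1L), ceiling(seq_len(B) / 512))
  } else {
    B <- as.integer(n_perm)
    chunks <- split(seq_len(B), ceiling(seq_len(B) / 512))
  }

  null_max <- numeric(B); null_min <- numeric(B)
  k <- 0L
  with_local_seed(seed, {
    for (ch in chunks) {
      S <- if (exact) signs_of(ch) else
        matrix(sample(c(-1, 1), length(ch) * n, replace = TRUE),
               length(ch), n)
      Tm <- t_block(S, Dv, ss)
      for (r in seq_len(nrow(Tm))) {
        k <- k + 1L
        ext <- extreme_masses(Tm[r, ], tcrit, nbrs, n_valid)
        null_max[k] <- ext[1]; null_min[k] <- ext[2]
      }
    }
  })

  for (i in seq_along(clusters)) {
    m <- clusters[[i]]$mass
    p <- if (m > 0) {
      if (exact) mean(null_max >= m) else (1 + sum(null_max >= m)) / (1 + B)
    } else {
      if (exact) mean(null_min <= m) else (1 + sum(null_min <= m)) / (1 + B)
    }
    clusters[[i]]$p <- p
    clusters[[i]]$p_corrected <- min(1, p * bonferroni)
    clusters[[i]]$significant <- clusters[[i]]$p_corrected <= tail_alpha
  }

  res <- list(clusters = clusters, tmap = tmap,
              null_max = null_max, null_min = null_min,
              n_perm = B, seed = as.integer(seed),
              bonferroni = bonferroni, tail_alpha = tail_alpha,
              alpha_triplet = alpha_triplet, exact = exact,
              n_subjects = n)
  class(res) <- "wm_cluster_result"
  res
}

#' @export
print.wm_cluster_result <- function(x, ...) {
  cat(sprintf("<wm_cluster_result> %d subject pairs, %s%d permutations, triplet alpha %g, tail alpha %g%s\n",
              x$n_subjects, if (x$exact) "exact " else "", x$n_perm,
              x$alpha_triplet, x$tail_alpha,
              if (x$bonferroni != 1) sprintf(", Bonferroni x%g", x$bonferroni) else ""))
  if (!length(x$clusters)) {
    cat("  no supra-threshold clusters\n")
    return(invisible(x))
  }
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  cluster %d (%s): %d triplets, mass %.2f, p = %.4g, corrected p = %.4g%s\n",
                i, if (cl$sign > 0) "pos" else "neg", nrow(cl$triplets),
                cl$mass, cl$p, cl$p_corrected,
                if (cl$significant) " *" else ""))
    cat(sprintf("    channels %s; %g-%g Hz; %.2f-%.2f s\n",
                paste(sort(unique(cl$triplets$channel)), collapse = "/"),
                min(cl$triplets$freq), max(cl$triplets$freq),
                min(cl$triplets$time), max(cl$triplets$time)))
  }
  invisible(x)
}

#' Significant clusters of a permutation result
#' @param x a `wm_cluster_result`.
#' @return The subset of clusters flagged significant.
#' @export
significant_clusters <- function(x) {
  stopifnot(inherits(x, "wm_cluster_result"))
  Filter(function(cl) isTRUE(cl$significant), x$clusters)
}

#' Restrict per-subject arrays to an analysis box
#'
#' Convenience subsetting of condition-mean arrays (channels x freqs x
#' times, with dimnames) to the channel set, frequency range and time range
#' of a configured analysis box.
#'
#' @param arr array from [tfr_mean()].
#' @param channels channel labels to keep.
#' @param f_lim,t_lim inclusive ranges (Hz, s); `NULL` keeps everything.
#' @return The subset array, dimnames preserved.
#' @export
subset_box <- function(arr, channels = NULL, f_lim = NULL, t_lim = NULL) {
  dn <- dimnames(arr)
  ic <- if (is.null(channels)) seq_len(dim(arr)[1]) else match(channels, dn[[1]])
  if (anyNA(ic)) stop("unknown channel(s)")
  fr <- as.numeric(dn[[2]]); tm <- as.numeric(dn[[3]])
  jf <- if (is.null(f_lim)) seq_along(fr) else
    which(fr >= f_lim[1] - 1e-9 & fr <= f_lim[2] + 1e-9)
  jt <- if (is.null(t_lim)) seq_along(tm) else
    which(tm >= t_lim[1] - 1e-9 & tm <= t_lim[2] + 1e-9)
  arr[ic, jf, jt, drop = FALSE]
}
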