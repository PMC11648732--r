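# Shared fixtures and independent oracles used across the suite. Oracles are
# deliberately naive (flood fill, sort-based ranking, flatten-and-mean) and
# independent of the implementation paths they check.

# small, fast site profile; tiny volumes keep generation and training cheap
tiny_profile <- function(site_id = "T", n_cases = 4L, seed = 11L,
                         shape = c(16L, 16L, 16L),
                         spacing = c(2, 2, 2), style = "manual",
                         frag = 0L,
                         prev = c(cons = 0.9, ggo = 0.8, pe = 0.5)) {
  site_profile(site_id = site_id, n_cases = n_cases, voxel_spacing = spacing,
               class_prevalence = prev, annotation_style = style,
               fragmentation_level = frag, shape = shape, rng_seed = seed)
}

# a tiny federation: datasets, split, shared config and preprocessed subsets
tiny_federation <- function(sites = c("X", "Y"), n_cases = 4L, seed = 5L) {
  datasets <- lapply(seq_along(sites), function(i)
    suppressWarnings( # tiny cohorts may have a degenerate PE stratum
      split_train_test(generate_site(tiny_profile(sites[i], n_cases,
                                                  seed = seed + i)),
                       0.75, seed = seed)))
  names(datasets) <- sites
  train_raw <- lapply(datasets, subset_split, "train")
  cfg <- configure_model(aggregate_fingerprints(lapply(train_raw,
                                                       compute_fingerprint)),
                         "desk")
  list(datasets = datasets, config = cfg,
       train = lapply(train_raw, preprocess_dataset, config = cfg),
       test = lapply(lapply(datasets, subset_split, "test"),
                     preprocess_dataset, config = cfg))
}

# brute-force connected components by BFS over an adjacency rule
cc_count_bfs <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  idx <- which(mask != 0)
  if (!length(idx)) return(0L)
  coords <- arrayInd(idx, d)
  key <- function(p) paste(p, collapse = ",")
  remaining <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(coords))) assign(key(coords[r, ]), coords[r, ],
                                          envir = remaining)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, ,
                                       drop = FALSE]
  n <- 0L
  while (length(ls(remaining))) {
    n <- n + 1L
    seedk <- ls(remaining)[1]
    queue <- list(get(seedk, envir = remaining))
    rm(list = seedk, envir = remaining)
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        k <- key(q)
        if (exists(k, envir = remaining)) {
          queue[[length(queue) + 1L]] <- get(k, envir = remaining)
          rm(list = k, envir = remaining)
        }
      }
    }
  }
  n
}

# naive counting-based rank aggregation oracle: in each (site, metric)
# column a method's fractional rank is (#strictly better) + (1 + #tied) / 2;
# the overall rank is the plain mean over all columns
rank_oracle <- function(means, orientations) {
  dn <- dimnames(means)
  r_sum <- setNames(numeric(dim(means)[1]), dn[[1]])
  ncols <- 0L
  for (s in seq_len(dim(means)[2])) for (m in seq_len(dim(means)[3])) {
    v <- means[, s, m]
    key <- if (orientations[dn[[3]][m]] == "higher") -v else v
    pos <- vapply(key, function(x)
      sum(key < x) + (1 + sum(key == x)) / 2, 0)
    r_sum <- r_sum + pos
    ncols <- ncols + 1L
  }
  r_sum / ncols
}

# one-hot probability map for a given label mask
one_hot_map <- function(mask, K = 4L) {
  d <- dim(mask)
  p <- array(0, dim = c(d, K))
  m <- matrix(0, prod(d), K)
  m[cbind(seq_len(prod(d)), as.integer(mask) + 1L)] <- 1
  structure(array(m, dim = c(d, K)), class = "fsb_prob_map")
}

# random valid probability map
random_prob_map <- function(d = c(4, 4, 4), K = 4L, seed = 1L) {
  set.seed(seed)
  m <- matrix(stats::rexp(prod(d) * K), ncol = K)
  m <- m / rowSums(m)
  structure(array(m, dim = c(d, K)), class = "fsb_prob_map")
}

# tiny binary mask helper: place foreground voxels at given (i,j,k) rows
mask_at <- function(shape, at) {
  m <- array(0L, dim = shape)
  for (r in seq_len(nrow(at))) m[at[r, 1], at[r, 2], at[r, 3]] <- 1L
  m
}
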