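# Independent oracles and fixture builders used across the suite.
# Oracles deliberately use different algorithms/libraries than the
# implementation they check.

# ---- geometry fixtures ------------------------------------------------------

# annulus mask (TRUE on the ring) centred in an n x n raster
make_annulus <- function(n = 40, r_in = 8, r_out = 14,
                         cx = (n + 1) / 2, cy = (n + 1) / 2) {
  cc <- matrix(rep(1:n, each = n), n)
  rr <- matrix(rep(1:n, times = n), n)
  d2 <- (rr - cy)^2 + (cc - cx)^2
  d2 <= r_out^2 & d2 > r_in^2
}

disc_pixels <- function(n, cx, cy, r) {
  cc <- matrix(rep(1:n, each = n), n)
  rr <- matrix(rep(1:n, times = n), n)
  which((rr - cy)^2 + (cc - cx)^2 <= r^2)
}

# probability stack with given myelin mask; remaining mass on axoplasm
# inside `axo_mask` (defaults to everything off-myelin) and membrane
# elsewhere
toy_prob_stack <- function(myelin_mask, axo_mask = NULL, pixel_size_um = 1) {
  d <- dim(myelin_mask)
  if (is.null(axo_mask)) axo_mask <- !myelin_mask
  p <- array(0, c(d[1], d[2], 3))
  p[, , 1][myelin_mask] <- 1
  p[, , 2][!myelin_mask & axo_mask] <- 1
  p[, , 3][!myelin_mask & !axo_mask] <- 1
  prob_stack(p, pixel_size_um)
}

# small candidate tibble from a list of pixel-index sets
make_candidates <- function(px_list, dims, stage = "inner_region",
                            state = "selected", pixel_size_um = 1) {
  tbl <- tibble::tibble(
    label = seq_along(px_list), stage = stage,
    state = rep_len(state, length(px_list)), pixels = px_list)
  myelinseg:::new_roi_candidates(tbl, dims, pixel_size_um)
}

# ---- stage-2 oracle: unweighted BFS on the pixel graph via igraph ----------

bfs_flood_oracle <- function(seed_lab, domain) {
  stopifnot(requireNamespace("igraph", quietly = TRUE))
  nr <- nrow(seed_lab); nc <- ncol(seed_lab)
  dom <- domain | seed_lab > 0L
  nodes <- which(dom)
  map <- integer(nr * nc); map[nodes] <- seq_along(nodes)
  edges <- list()
  offs <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0), ,
               drop = FALSE]   # forward half-neighbourhood
  rc <- cbind((nodes - 1L) %% nr + 1L, (nodes - 1L) %/% nr + 1L)
  for (k in seq_len(nrow(offs))) {
    r2 <- rc[, 1] + offs[k, 1]; c2 <- rc[, 2] + offs[k, 2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- dom[nb]
    edges[[k]] <- cbind(map[nodes[ok][ok2]], map[nb[ok2]])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  if (!is.null(el) && nrow(el)) g <- igraph::add_edges(g, t(el))
  out <- matrix(0L, nr, nc)
  seed_ids <- sort(unique(seed_lab[seed_lab > 0L]))
  if (!length(seed_ids)) return(out)
  dmin <- matrix(Inf, length(seed_ids), length(nodes))
  for (si in seq_along(seed_ids)) {
    sv <- map[which(seed_lab == seed_ids[si] & dom)]
    d <- igraph::distances(g, v = sv, to = seq_along(nodes))
    dmin[si, ] <- apply(d, 2, min)
  }
  reach <- apply(dmin, 2, min) < Inf
  best <- apply(dmin, 2, which.min)   # ties: first = lowest label index
  out[nodes[reach]] <- seed_ids[best[reach]]
  out
}

# random 64 x 64 myelin mask + seed labels for the flood oracle
random_flood_case <- function(seed, n = 64) {
  set.seed(seed)
  noise <- matrix(stats::rnorm(n * n), n)
  sm <- filter_gaussian(noise, 3)
  mask <- sm > stats::quantile(sm, 0.6)
  k <- sample(2:5, 1)
  seed_lab <- matrix(0L, n, n)
  for (i in seq_len(k)) {
    r <- sample(3:(n - 4), 1); c <- sample(3:(n - 4), 1)
    seed_lab[r:(r + 2), c:(c + 2)] <- i
  }
  mask[seed_lab > 0L] <- FALSE
  list(seed_lab = seed_lab, mask = mask)
}

# ---- matching oracle: exhaustive best one-to-one assignment ----------------

# maximises pair count, then total IoU, over all one-to-one matchings with
# IoU >= threshold; recursion over targets (feasible for <= 6 objects)
brute_force_match <- function(tlab, plab, threshold) {
  ov <- myelinseg:::overlap_table(tlab, plab)
  ov <- ov[ov$iou >= threshold, ]
  t_ids <- sort(unique(ov$target))
  best <- list(n = -1, iou = -1, pairs = NULL)
  recurse <- function(i, used_p, pairs) {
    if (i > length(t_ids)) {
      n <- nrow(pairs)
      s <- if (n) sum(pairs$iou) else 0
      if (n > best$n || (n == best$n && s > best$iou)) {
        best <<- list(n = n, iou = s, pairs = pairs)
      }
      return(invisible())
    }
    cand <- ov[ov$target == t_ids[i] & !(ov$prediction %in% used_p), ]
    recurse(i + 1, used_p, pairs)   # leave target unmatched
    for (j in seq_len(nrow(cand))) {
      recurse(i + 1, c(used_p, cand$prediction[j]),
              rbind(pairs, cand[j, c("target", "prediction", "iou")]))
    }
  }
  recurse(1, integer(),
          tibble::tibble(target = integer(), prediction = integer(),
                         iou = numeric()))
  best
}

# random toy instance maps with up to `max_obj` rectangular objects
random_toy_maps <- function(seed, n = 24, max_obj = 6) {
  set.seed(seed)
  mk <- function(jitter) {
    lab <- matrix(0L, n, n)
    k <- sample(1:max_obj, 1)
    for (i in seq_len(k)) {
      w <- sample(3:7, 1); h <- sample(3:7, 1)
      r <- sample(seq(1, n - h, by = 4), 1)
      c <- sample(seq(1, n - w, by = 4), 1)
      r <- min(max(1, r + jitter()), n - h)
      c <- min(max(1, c + jitter()), n - w)
      lab[r:(r + h), c:(c + w)] <- i
    }
    lab
  }
  t <- mk(function() 0L)
  set.seed(seed)          # same layout, jittered
  p <- mk(function() sample(-1:1, 1))
  list(target = instance_map(t, "fibre"), prediction = instance_map(p, "fibre"))
}

# ---- dense convolution oracle ----------------------------------------------

# direct dense 2D convolution with mirrored boundary, for kernel oracles
dense_conv2 <- function(x, kern) {
  nr <- nrow(x); nc <- ncol(x)
  kr <- (nrow(kern) - 1) / 2; kc <- (ncol(kern) - 1) / 2
  refl <- function(i, n) ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
  out <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    acc <- 0
    for (dr in -kr:kr) for (dc in -kc:kc) {
      acc <- acc + kern[dr + kr + 1, dc + kc + 1] *
        x[refl(r + dr, nr), refl(c + dc, nc)]
    }
    out[r, c] <- acc
  }
  out
}

# ---- hierarchy fuzz cases ---------------------------------------------------

# random fibre/inner/axon candidate sets exercising clipping, composite
# reduction and duplication
random_hierarchy_case <- function(seed, n = 48) {
  set.seed(seed)
  k <- sample(1:4, 1)
  fibre_lab <- matrix(0L, n, n)
  inner_list <- list(); axon_list <- list()
  centres <- expand.grid(r = c(12, 34), c = c(12, 34))
  centres <- centres[sample(nrow(centres), k), , drop = FALSE]
  for (i in seq_len(k)) {
    r0 <- centres$r[i] + sample(-2:2, 1)
    c0 <- centres$c[i] + sample(-2:2, 1)
    rf <- sample(7:10, 1)
    fib <- disc_pixels(n, c0, r0, rf)
    fibre_lab[fib] <- i
    # inner: offset disc, possibly poking out of the fibre (clipping) and
    # possibly with a detached fragment (composite reduction)
    inn <- disc_pixels(n, c0 + sample(-3:3, 1), r0 + sample(-3:3, 1),
                       sample(3:(rf - 2), 1))
    if (stats::runif(1) < 0.3) {
      frag <- disc_pixels(n, min(n - 2, c0 + rf + 3), r0, 1)
      inn <- union(inn, frag)
    }
    inner_list[[i]] <- inn
    # axon present ~70% of the time, sometimes overflowing the inner disc
    if (stats::runif(1) < 0.7) {
      axon_list[[length(axon_list) + 1L]] <-
        disc_pixels(n, c0 + sample(-2:2, 1), r0 + sample(-2:2, 1),
                    sample(2:4, 1))
    }
  }
  list(
    inner = make_candidates(inner_list, c(n, n)),
    fibres = instance_map(fibre_lab, "fibre"),
    axons = if (length(axon_list)) {
      make_candidates(axon_list, c(n, n), stage = "axon")
    } else NULL)
}
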