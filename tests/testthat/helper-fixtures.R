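# Shared fixtures and independent oracles built in code at test time.

study_protocol <- function() mp2rage_protocol()

# small phantom + full noiseless pre/post pipeline, reused across tests
run_noiseless_pipeline <- function(shape = c(48, 48, 48), lesion_count = 4,
                                   el_fraction = 0.25, seed = 1,
                                   tissues = tissue_spec(), lookup = NULL,
                                   noise_sigma = 0, misalignment = NULL,
                                   lesion_radius_range = if (min(shape) < 48)
                                     c(2, 3) else c(3, 5)) {
  cfg <- phantom_config(shape = shape, lesion_count = lesion_count,
                        lesion_radius_range = lesion_radius_range,
                        el_fraction = el_fraction, seed = seed,
                        noise_sigma = noise_sigma, misalignment = misalignment)
  gt <- apply_gadolinium(build_phantom(cfg, tissues), mode = "direct")
  protocol <- study_protocol()
  if (is.null(lookup)) lookup <- build_lookup(protocol)
  pre <- simulate_acquisition(gt, protocol, phase = "pre")
  post <- simulate_acquisition(gt, protocol, phase = "post")
  rec_pre <- reconstruct_t1_map(pre$inv2, pre$uni, protocol, lookup)
  rec_post <- reconstruct_t1_map(post$inv2, post$uni, protocol, lookup)
  list(gt = gt, pre = pre, post = post, rec_pre = rec_pre, rec_post = rec_post,
       delta = compute_delta_t1(rec_pre$t1, rec_post$t1,
                                rec_pre$qc_flagged, rec_post$qc_flagged),
       lookup = lookup)
}

mask_median <- function(map, mask) {
  stats::median(map$data[mask], na.rm = TRUE)
}

# 6-connectivity connected-component count, independent of the generator's
# own lesion bookkeeping (igraph on the voxel adjacency graph)
count_components <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(0L)
  shp <- dim(mask)
  pos <- arrayInd(idx, shp)
  key <- function(p) (p[, 3] - 1) * shp[1] * shp[2] + (p[, 2] - 1) * shp[1] + p[, 1]
  inmask <- integer(prod(shp))
  inmask[idx] <- seq_along(idx)
  edges <- integer(0)
  for (d in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    nb <- sweep(pos, 2, d, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= shp[1] & nb[, 2] >= 1 & nb[, 2] <= shp[2] &
      nb[, 3] >= 1 & nb[, 3] <= shp[3]
    nb_id <- integer(nrow(nb))
    nb_id[ok] <- inmask[key(nb[ok, , drop = FALSE])]
    has <- nb_id > 0
    edges <- c(edges, rbind(seq_along(idx)[has], nb_id[has]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  as.integer(igraph::components(g)$no)
}

# exact two-sided matched-pairs Wilcoxon p by enumeration of sign patterns
wilcoxon_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# exact two-sided Mann-Whitney p by enumeration of group assignments
mann_whitney_exact_p <- function(a, b) {
  na <- length(a); pool <- c(a, b)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(length(pool), na)
  u_all <- apply(combs, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}
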