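# Phantom constructors and independent oracles used across the suite.

# concentric hemispherical shells as an lv_mesh (base ring at z = 0)
hemisphere_mesh <- function(r_endo = 25, r_epi = 35, n_circ = 48, n_long = 24) {
  u <- seq(0, 1, length.out = n_long)
  theta <- lvshape:::wrap_angle(2 * pi * (seq_len(n_circ) - 1L) / n_circ)
  phi <- (1 - u) * pi / 2      # pi/2 at base (equator), 0 at apex pole
  U <- rep(phi, each = n_circ)
  TH <- rep(theta, times = n_long)
  shell <- function(r) cbind(r * sin(U) * cos(TH), r * sin(U) * sin(TH),
                             -r * cos(U))
  structure(list(endo = shell(r_endo), epi = shell(r_epi), theta = theta,
                 u = u, n_circ = as.integer(n_circ), n_long = as.integer(n_long),
                 topology_id = sprintf("lvgrid-%dx%d-v1", n_circ, n_long)),
            class = "lv_mesh")
}

# number of 4-connected foreground components in a binary slice (flood fill)
n_components <- function(slice) {
  lab <- matrix(0L, nrow(slice), ncol(slice))
  comp <- 0L
  for (s in which(slice > 0)) {
    if (lab[s] > 0L) next
    comp <- comp + 1L
    queue <- s
    lab[s] <- comp
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i <- (cur - 1L) %% nrow(slice) + 1L
      j <- (cur - 1L) %/% nrow(slice) + 1L
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nrow(slice) && jj >= 1 && jj <= ncol(slice)) {
          k <- (jj - 1L) * nrow(slice) + ii
          if (slice[k] > 0 && lab[k] == 0L) { lab[k] <- comp; queue <- c(queue, k) }
        }
      }
    }
  }
  comp
}

# brute-force AUC by pair enumeration, ties counted one half
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
  s / (length(pos) * length(neg))
}

# independently coded Fisher LDA refit (no shrinkage): weights, pooled-score
# normalization and orientation toward the positive class
oracle_lda_z <- function(train_X, train_y, test_x) {
  A <- train_X[train_y == 0, , drop = FALSE]
  B <- train_X[train_y == 1, , drop = FALSE]
  SA <- crossprod(sweep(A, 2, colMeans(A)))
  SB <- crossprod(sweep(B, 2, colMeans(B)))
  Sw <- (SA + SB) / (nrow(A) + nrow(B))
  w <- solve(Sw, colMeans(B) - colMeans(A))
  sc <- train_X %*% w
  z <- (train_X %*% w - mean(sc)) / sd(sc)
  flip <- mean(z[train_y == 1]) < mean(z[train_y == 0])
  zt <- (sum(test_x * w) - mean(sc)) / sd(sc)
  if (flip) -zt else zt
}

# quick random-but-valid geometry parameter draw
random_params <- function() {
  lv_geometry_params(length_mm = 80 + rnorm(1, 0, 6),
                     endo_base_radius_mm = 25 + rnorm(1, 0, 2),
                     base_thickness_mm = 8 + rnorm(1, 0, 1),
                     septal_bump_amp_mm = max(4 + rnorm(1, 0, 1.5), 0),
                     apical_dilation = abs(0.05 + rnorm(1, 0, 0.03)),
                     lvot_inward_mm = abs(1 + rnorm(1, 0, 0.8)))
}

# small corresponded mesh cohort for shape-model tests
random_mesh_cohort <- function(n, n_circ = 16, n_long = 8) {
  lapply(seq_len(n), function(i) generate_lv_surface(random_params(),
                                                     n_circ, n_long))
}
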