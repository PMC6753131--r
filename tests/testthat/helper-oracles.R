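# Independent oracles and fixture builders shared across tests. Oracles are
# deliberately written as literal loops / naive algorithms so they share no
# code path with the implementation they check.

# per-vertex loop AED, independent of the vectorised implementation
aed_loop <- function(va, vb) {
  total <- 0
  for (i in seq_len(nrow(va)))
    total <- total + sqrt(sum((va[i, ] - vb[i, ])^2))
  total / nrow(va)
}

signed_error_loop <- function(vref, voth) {
  out <- numeric(nrow(vref))
  for (i in seq_len(nrow(vref))) {
    d <- sqrt(sum((vref[i, ] - voth[i, ])^2))
    out[i] <- if (vref[i, 3] >= voth[i, 3]) d else -d
  }
  out
}

# random proper rotation from a random axis and angle
random_rotation_oracle <- function() {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, -pi, pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_similarity <- function(scale_range = c(0.5, 2), trans_range = 50) {
  similarity_transform(random_rotation_oracle(),
                       stats::runif(1, scale_range[1], scale_range[2]),
                       stats::runif(3, -trans_range, trans_range))
}

# largest principal angle (degrees) between the column spaces of U1, U2
max_principal_angle <- function(U1, U2) {
  s <- svd(crossprod(U1, U2))$d
  acos(min(1, max(0, min(s)))) * 180 / pi
}

# mean silhouette width over a 2-D embedding with known labels
silhouette_mean <- function(Y, labels) {
  D <- as.matrix(stats::dist(Y))
  n <- nrow(Y)
  mean(vapply(seq_len(n), function(i) {
    same <- labels == labels[i] & seq_len(n) != i
    a <- mean(D[i, same])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(D[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0))
}

# small fixed test meshes
tetra_mesh <- function(id = "tetra") {
  trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
          rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)), id = id)
}

random_mesh <- function(n = 50, seed = 1) {
  set.seed(seed)
  v <- matrix(stats::rnorm(3 * n, sd = 10), n, 3)
  f <- cbind(seq_len(n - 2), seq_len(n - 2) + 1L, seq_len(n - 2) + 2L)
  trimesh(v, f, id = sprintf("random%d", seed))
}

small_template <- function(resolution = 14)
  make_template(generator_config(resolution = resolution))

# a smooth relief deformation of the template with the requested peak
# amplitude (mm); returns target vertices
relief_deformation <- function(tpl, amplitude, seed = 1, rank = 4) {
  set.seed(seed)
  B <- morphface:::smooth_basis(tpl$uv, rank, vertex_normals(tpl$mesh))
  f <- as.vector(B %*% stats::rnorm(rank))
  pk <- max(sqrt(rowSums(matrix(f, ncol = 3, byrow = TRUE)^2)))
  tpl$mesh$vertices + matrix(amplitude * f / pk, ncol = 3, byrow = TRUE)
}

landmarks_at <- function(vertices, idx, names, id = "lm")
  landmark_set(id, vertices[idx, , drop = FALSE], names)
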