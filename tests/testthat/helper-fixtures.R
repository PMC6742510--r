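# Shared fixtures: analytic shapes, tiny volumes, finite-difference helpers.

sphere_label <- function(shape, centre, radius, spacing = c(1, 1, 1)) {
  P <- sweep(weakreg:::grid_index(shape), 2, spacing, "*")
  volume(array(as.numeric(rowSums(sweep(P, 2, centre)^2) <= radius^2),
               dim = shape),
         spacing = spacing, is_label = TRUE)
}

random_volume <- function(shape, seed = NULL, spacing = c(1, 1, 1)) {
  if (!is.null(seed)) set.seed(seed)
  volume(array(rnorm(prod(shape)), dim = shape), spacing = spacing)
}

zero_ddf <- function(shape, spacing = c(1, 1, 1)) {
  ddf(array(0, dim = c(shape, 3L)), spacing = spacing)
}

constant_ddf <- function(shape, disp, spacing = c(1, 1, 1)) {
  ddf(array(rep(disp, each = prod(shape)), dim = c(shape, 3L)),
      spacing = spacing)
}

smooth_random_ddf <- function(shape, amp = 0.5, sigma = 2, seed = 1,
                              spacing = c(1, 1, 1)) {
  set.seed(seed)
  u <- array(0, dim = c(shape, 3L))
  for (cc in 1:3) {
    u[, , , cc] <- gaussian_filter(array(rnorm(prod(shape)), dim = shape),
                                   sigma, spacing)
  }
  mag <- sqrt(rowSums(matrix(u, ncol = 3)^2))
  if (max(mag) > 0) u <- u * amp / max(mag)
  ddf(u, spacing = spacing)
}

# leaf-path utilities for finite-difference checks on parameter trees
tree_paths <- function(tr) {
  paths <- list()
  walk <- function(t, pre) {
    if (is.list(t)) for (i in seq_along(t)) walk(t[[i]], c(pre, i))
    else paths[[length(paths) + 1]] <<- pre
  }
  walk(tr, integer())
  paths
}

tree_get <- function(tr, pth) {
  for (i in pth) tr <- tr[[i]]
  tr
}

tree_set <- function(tr, pth, val) {
  if (length(pth) == 1) tr[[pth]] <- val
  else tr[[pth[1]]] <- tree_set(tr[[pth[1]]], pth[-1], val)
  tr
}
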