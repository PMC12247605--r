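# shared fixtures, built once per test run

tv <- function(v) sum(abs(diff(v)))

.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

small_phantom <- function() fixture("small_phantom", function()
  make_multishell_phantom(c(24, 24, 8)))

bench_phantom <- function() fixture("bench_phantom", function()
  make_multishell_phantom(c(40, 40, 10)))

proto <- function() fixture("proto", default_protocol)

# tiny 3-shell protocol for fast fitting tests (still rank-22 capable)
mini_proto <- function() fixture("mini_proto", function() {
  bv <- c(rep(0, 2), rep(1000, 12), rep(2000, 16))
  dirs <- rbind(matrix(0, 2, 3),
                dkiprep:::sphere_spiral(12, 0.2),
                dkiprep:::sphere_spiral(16, 0.6))
  gradient_table(bv, dirs)
})

# forward DKI signals for one tensor pair over a protocol
forward_vol <- function(s0, dt, kt, grad, grid = c(3, 3, 3)) {
  sig <- dkiprep:::forward_signal(s0, dt, kt, grad)
  data <- array(rep(sig, each = prod(grid)), c(grid, length(sig)))
  dwi_volume(data, grad = grad)
}

# random symmetric positive-definite diffusion tensor (um^2/ms scale) and a
# compatible kurtosis tensor in the fitted (MD^2 * W) parameterization
random_tensor_pair <- function() {
  A <- matrix(rnorm(9, sd = 0.4), 3)
  D <- crossprod(A) + diag(3) * 0.4
  dt <- c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  kp <- runif(1, 0.2, 1.2); kr <- runif(1, 0.2, 2)
  ev <- eigen(D, symmetric = TRUE)$values
  kt <- dkiprep:::kt_axial(u, kp, kr, ev[1], mean(ev[2:3]))
  list(dt = dt, kt = kt)
}
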