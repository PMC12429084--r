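# Shared fixture builders: everything is generated in code at test time.

# Small scheme for fast fits: 1 b0 + n directions at b = 1000
small_scheme <- function(n_dir = 12L) default_scheme(n_dir = n_dir)

# Uniform-tensor DWI volume on a small grid (noise-free forward model)
uniform_tensor_dwi <- function(D, dims = c(3L, 3L, 3L),
                               scheme = small_scheme(), s0 = 1000,
                               voxel_size = 2.5) {
  sig <- simulate_signal(D, scheme, s0)
  nvol <- length(scheme$bvalues)
  arr <- array(rep(sig, each = prod(dims)), dim = c(dims, nvol))
  dwi_volume(arr, scheme, voxel_size = voxel_size)
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

# Extract the fitted tensor of one voxel as a 3x3 matrix
voxel_tensor <- function(field, i = 1L, j = 1L, k = 1L) {
  matrix(c(field$dxx[i, j, k], field$dxy[i, j, k], field$dxz[i, j, k],
           field$dxy[i, j, k], field$dyy[i, j, k], field$dyz[i, j, k],
           field$dxz[i, j, k], field$dyz[i, j, k], field$dzz[i, j, k]),
         3, 3)
}

# Full-enumeration two-sided Fisher p for a 2x2 table: sum of hypergeometric
# probabilities not exceeding the observed table's (relative slack 1e-7,
# matching the conventional comparison rule).
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  lo <- max(0L, c1 - (n - r1))
  hi <- min(r1, c1)
  dens <- stats::dhyper(lo:hi, r1, n - r1, c1)
  sum(dens[dens <= dens[a - lo + 1L] * (1 + 1e-7)])
}
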