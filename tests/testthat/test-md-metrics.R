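# small helper: protein-only complex with n CA atoms at given coordinates
ca_complex <- function(xyz, ligand = NULL) {
  prot <- purrr::map_dfr(seq_len(nrow(xyz)), function(i) {
    atom_row(i, "CA", "C", "GLY", i, xyz[i, ])
  })
  lig <- if (is.null(ligand)) atom_row(900, "O1", "O", "LIG", 1, c(999, 999, 999),
    chain = "L")[0, ] else ligand
  new_complex(prot, lig, "LIG")
}

test_that("Kabsch superposition recovers zero RMSD for rigid copies", {
  set.seed(5)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_superpose(x, x)$rmsd, 0, tolerance = 1e-10)
  th <- pi / 2
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
    byrow = TRUE)
  y <- x %*% rot + matrix(c(4, -2, 7), 10, 3, byrow = TRUE)
  fit <- kabsch_superpose(y, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  # returned transform actually maps mobile onto reference
  mapped <- y %*% fit$rotation + matrix(fit$translation, 10, 3, byrow = TRUE)
  expect_equal(mapped, x, tolerance = 1e-8)
})

test_that("Kabsch RMSD equals brute-force minimisation over rotations", {
  set.seed(9)
  x <- matrix(rnorm(12), 4, 3)
  y <- x + matrix(rnorm(12, 0, 0.3), 4, 3)
  ours <- kabsch_superpose(y, x)$rmsd
  # independent oracle: numeric minimisation over Euler angles after centering
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  euler_rot <- function(p) {
    ca <- cos(p[1]); sa <- sin(p[1]); cb <- cos(p[2]); sb <- sin(p[2])
    cg <- cos(p[3]); sg <- sin(p[3])
    rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
    rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    rz1 %*% ry %*% rz2
  }
  obj <- function(p) sqrt(mean(rowSums((yc %*% euler_rot(p) - xc)^2)))
  best <- Inf
  for (s in 1:20) {
    p0 <- runif(3, -pi, pi)
    o <- optim(p0, obj, method = "Nelder-Mead",
      control = list(reltol = 1e-14, maxit = 5000))
    best <- min(best, o$value)
  }
  expect_equal(ours, best, tolerance = 1e-6)
  expect_lte(ours, best + 1e-8)  # Kabsch is the true minimum
})

test_that("Kabsch rejects degenerate inputs", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
    "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "Degenerate")
})

test_that("RMSD series is zero for identical and rigidly moved frames", {
  set.seed(11)
  xyz <- matrix(rnorm(60, sd = 4), 20, 3)
  cx <- ca_complex(xyz)
  n <- 5
  coords <- array(0, dim = c(n, 20, 3))
  rot <- random_rotation(3)
  for (m in 1:n) {
    moved <- xyz %*% (if (m %% 2) diag(3) else rot) +
      matrix(c(m, -m, 2 * m), 20, 3, byrow = TRUE)
    coords[m, , ] <- moved
  }
  tr <- new_trajectory(cx, coords, times = (0:(n - 1)) * 10)
  rs <- rmsd_series(tr, selection = 1:20)
  expect_equal(rs$value, rep(0, n), tolerance = 1e-8)
  expect_equal(rs$time, (0:(n - 1)) * 10)
})

test_that("jittered RMSD matches an independent Monte-Carlo oracle", {
  set.seed(13)
  n_at <- 200
  xyz <- matrix(rnorm(3 * n_at, sd = 8), n_at, 3)
  cx <- ca_complex(xyz)
  sigma <- 0.15
  tr <- gen_jitter_trajectory(cx, sigma = sigma, n_frames = 300, seed = 31)
  ours <- mean(rmsd_series(tr, selection = seq_len(n_at))$value[-1])
  # oracle: fresh reference/frame draws at matched sigma and atom count,
  # superposed by bio3d's independent fitter
  oracle <- mean(vapply(1:300, function(i) {
    ref_jit <- xyz + matrix(rnorm(3 * n_at, 0, sigma), n_at, 3)
    frame <- xyz + matrix(rnorm(3 * n_at, 0, sigma), n_at, 3)
    fitted <- suppressWarnings(bio3d::fit.xyz(as.vector(t(ref_jit)),
      matrix(as.vector(t(frame)), nrow = 1)))
    sqrt(mean(colSums(matrix((fitted - as.vector(t(ref_jit)))^2, nrow = 3))))
  }, double(1)))
  expect_equal(ours, oracle, tolerance = 0.05 * oracle)
})

test_that("RMSF is zero for constant trajectories and localises mobility", {
  set.seed(17)
  xyz <- matrix(rnorm(90, sd = 5), 30, 3)
  cx <- ca_complex(xyz)
  const <- gen_jitter_trajectory(cx, sigma = 0, n_frames = 20, seed = 1)
  prof <- rmsf_profile(const, selection = 1:30)
  expect_equal(prof$value, rep(0, 30), tolerance = 1e-10)

  # one mobile atom among fixed atoms
  coords <- array(rep(xyz, each = 200), dim = c(200, 30, 3))
  coords[, 7, 1] <- coords[, 7, 1] + rnorm(200, 0, 0.8)
  tr <- new_trajectory(cx, coords, times = 0:199)
  prof2 <- rmsf_profile(tr, selection = 1:30)
  expect_gt(prof2$value[7], 0.3)
  expect_lt(max(prof2$value[-7]), 0.1)
  expect_warning(
    rmsf_profile(new_trajectory(cx, coords[1, , , drop = FALSE], times = 0),
      selection = 1:30),
    "zero"
  )
})

test_that("RMSF of isotropic jitter approaches sqrt(3) * sigma", {
  set.seed(19)
  xyz <- matrix(rnorm(150, sd = 6), 50, 3)
  cx <- ca_complex(xyz)
  tr <- gen_jitter_trajectory(cx, sigma = 0.1, n_frames = 2000, seed = 7)
  prof <- rmsf_profile(tr, selection = 1:50)
  expect_equal(mean(prof$value), sqrt(3) * 0.1, tolerance = 0.05)
})

test_that("RMSF is invariant under frame reordering", {
  set.seed(23)
  xyz <- matrix(rnorm(60, sd = 4), 20, 3)
  cx <- ca_complex(xyz)
  tr <- gen_jitter_trajectory(cx, sigma = 0.2, n_frames = 50, seed = 5)
  perm <- sample(50)
  tr2 <- new_trajectory(cx, tr$coords[perm, , , drop = FALSE], times = tr$times)
  # the single re-alignment pass leaves a sub-1e-4 frame-order dependence
  expect_equal(rmsf_profile(tr, selection = 1:20)$value,
    rmsf_profile(tr2, selection = 1:20)$value, tolerance = 1e-4)
})

test_that("hydrogen-bond counting over frames matches the plant and the profiler", {
  # one protein polar atom only, apolar neighbours on the -x side so the
  # planted ligand position (+x of the partner) sees a single polar pair
  prot <- dplyr::bind_rows(
    atom_row(1, "OD1", "O", "ASN", 101, c(0, 0, 0)),
    atom_row(2, "CG", "C", "ASN", 101, c(-1.4, 0, 0)),
    atom_row(3, "CB", "C", "ASN", 101, c(-2.8, 0, 0))
  )
  lig <- dplyr::bind_rows(
    atom_row(100, "O1", "O", "LIG", 1, c(12, 0, 0), chain = "L"),
    atom_row(101, "C1", "C", "LIG", 1, c(13.4, 0, 0), chain = "L")
  )
  cx <- new_complex(prot, lig, "LIG")
  tr <- gen_jitter_trajectory(cx, sigma = 0.05, n_frames = 1000,
    planted_hbond_fraction = 0.6, seed = 9)
  hb <- hbond_count_series(tr)
  expect_equal(mean(hb$value), 0.6, tolerance = 1e-12)
  # frame-wise consistency with the profiler on a subsample
  for (m in c(1, 10, 250, 999)) {
    cxm <- flavoscreen:::frame_complex(tr, m)
    expect_equal(hb$value[m],
      sum(profile_complex(cxm)$contacts$type == "hbond"))
  }
  # ligand far away in all frames -> all zeros
  far <- cx
  far$ligand$x <- far$ligand$x + 100
  tr0 <- gen_jitter_trajectory(far, sigma = 0.05, n_frames = 50, seed = 2)
  expect_equal(hbond_count_series(tr0)$value, rep(0, 50))
})

test_that("two planted bonds in every frame give a constant count of 2", {
  prot <- dplyr::bind_rows(
    atom_row(1, "OD1", "O", "ASN", 101, c(0, 0, 3.0)),
    atom_row(2, "OD1", "O", "ASN", 102, c(0, 0, -3.0))
  )
  lig <- atom_row(100, "O1", "O", "LIG", 1, c(0, 0, 0), chain = "L")
  cx <- new_complex(prot, lig, "LIG")
  tr <- gen_jitter_trajectory(cx, sigma = 0, n_frames = 25, seed = 1)
  expect_equal(hbond_count_series(tr)$value, rep(2, 25))
})

test_that("SASA of isolated spheres is analytic and additive", {
  one <- shrake_rupley_sasa(tibble::tibble(x = 0, y = 0, z = 0, element = "C"),
    n_points = 960)
  expect_equal(one$total, 4 * pi * 3.1^2, tolerance = 0.01 * 4 * pi * 3.1^2)

  two <- shrake_rupley_sasa(
    tibble::tibble(x = c(0, 100), y = 0, z = 0, element = c("C", "O")),
    n_points = 960
  )
  o_alone <- shrake_rupley_sasa(
    tibble::tibble(x = 0, y = 0, z = 0, element = "O"), n_points = 960)
  expect_equal(two$total, one$total + o_alone$total, tolerance = 1e-9)

  buried <- shrake_rupley_sasa(
    tibble::tibble(x = c(0, 0.4), y = 0, z = 0, element = c("C", "H")),
    n_points = 960
  )
  expect_equal(buried$per_atom$area[2], 0)
  expect_error(shrake_rupley_sasa(
    tibble::tibble(x = 0, y = 0, z = 0, element = "Xx")), "Xx")
})

test_that("SASA converges with point count and decreases on approach", {
  set.seed(29)
  cluster <- tibble::tibble(
    x = rnorm(20, sd = 2.5), y = rnorm(20, sd = 2.5), z = rnorm(20, sd = 2.5),
    element = sample(c("C", "N", "O"), 20, replace = TRUE)
  )
  coarse <- shrake_rupley_sasa(cluster, n_points = 960)$total
  fine <- shrake_rupley_sasa(cluster, n_points = 10000)$total
  expect_lt(abs(coarse - fine) / fine, 0.01)

  seps <- c(8, 6, 4, 3, 2, 1)
  totals <- vapply(seps, function(s) {
    shrake_rupley_sasa(tibble::tibble(x = c(0, s), y = 0, z = 0,
      element = "C"), n_points = 2000)$total
  }, double(1))
  expect_true(all(diff(totals) <= 1e-9))
})

test_that("distribution summaries use linear-interpolation quartiles", {
  s <- summarize_distribution(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)

  const <- summarize_distribution(rep(7, 10))
  expect_equal(const$min, 7)
  expect_equal(const$max, 7)
  expect_equal(const$median, 7)
  expect_equal(const$sd, 0)

  set.seed(37)
  norm <- summarize_distribution(rnorm(1e4))
  expect_lt(abs(norm$median), 0.05)
  expect_true(with(norm, min <= q1 && q1 <= median && median <= q3 && q3 <= max))
  expect_error(summarize_distribution(numeric(0)), "empty")
})
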