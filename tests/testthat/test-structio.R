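test_that("PDB parsing keeps Calpha-less residues and drops hetero records", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_mixed_pdb(f)
  m <- read_structure(f)
  expect_s3_class(m, "structure_model")
  expect_equal(n_residues(m), 4)           # ligand excluded
  expect_equal(n_residues(m, with_ca = TRUE), 3)
  expect_false(m$residues$has_ca[m$residues$resnum == 4])
  expect_true(all(m$residues$has_ca[m$residues$resnum %in% 1:3]))
})

test_that("single-residue file parses as a one-residue model", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line("ATOM", 1, "CA", "ALA", "A", 7, 1, 2, 3, "C"), "END"), f)
  m <- read_structure(f)
  expect_equal(n_residues(m), 1)
  expect_true(m$residues$has_ca)
  expect_equal(unname(unlist(m$residues[, c("x", "y", "z")])), c(1, 2, 3))
})

test_that("written toy models round-trip through the PDB parser", {
  m <- make_toy_structure(40, "random-walk", seed = 5, resnames = "LYS",
                          start_resnum = 100)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(m, f)
  m2 <- read_structure(f)
  expect_equal(n_residues(m2), 40)
  expect_equal(m2$residues$resnum, m$residues$resnum)
  expect_lt(max(abs(ca_coords(m2) - ca_coords(m))), 1e-2)  # PDB precision
})

test_that("ca_distance is Euclidean, symmetric, and errors are typed", {
  res <- data.frame(chain = "A", resnum = 1:3, resname = "GLY",
                    x = c(0, 3, NA), y = c(0, 4, NA), z = c(0, 0, NA),
                    has_ca = c(TRUE, TRUE, FALSE))
  m <- structure_model(res)
  expect_equal(ca_distance(m, 1, 2), 5)             # 3-4-5 triangle
  expect_equal(ca_distance(m, 1, 1), 0)
  expect_equal(ca_distance(m, 2, 1), ca_distance(m, 1, 2))
  expect_error(ca_distance(m, 1, 99), class = "structkit_unmodeled")
  expect_error(ca_distance(m, 1, 3), class = "structkit_no-calpha")
})

test_that("ca_distance matches straight-line recomputation on random pairs", {
  set.seed(42)
  m <- make_toy_structure(60, "random-walk", seed = 9)
  co <- ca_coords(m)
  for (k in 1:100) {
    ij <- sample(60, 2)
    expect_equal(ca_distance(m, ij[1], ij[2]),
                 sqrt(sum((co[ij[1], ] - co[ij[2], ])^2)), tolerance = 1e-9)
  }
  # triangle inequality on random triples
  for (k in 1:50) {
    t3 <- sample(60, 3)
    expect_lte(ca_distance(m, t3[1], t3[3]),
               ca_distance(m, t3[1], t3[2]) + ca_distance(m, t3[2], t3[3]) + 1e-12)
  }
})

test_that("superpose is exact on self and on rigid copies", {
  m <- make_toy_structure(30, "random-walk", seed = 1)
  sp <- superpose(m, m)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  expect_equal(sp$n_atoms, 30)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)

  set.seed(7)
  for (k in 1:10) {
    R <- random_rotation(); t <- rnorm(3, sd = 20)
    moved <- apply_transform(m, list(rotation = R, translation = t))
    sp <- superpose(moved, m)
    expect_lt(sp$rmsd, 1e-6)
    expect_equal(sp$rotation, R, tolerance = 1e-6)
    # orthonormal, det +1
    expect_equal(t(sp$rotation) %*% sp$rotation, diag(3), tolerance = 1e-9)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  }
})

test_that("superpose RMSD is invariant under rigid motion of either input", {
  set.seed(11)
  a <- make_toy_structure(40, "random-walk", seed = 2)
  b <- a
  i <- b$residues$has_ca
  b$residues$x[i] <- b$residues$x[i] + rnorm(40, sd = 0.5)
  b$residues$y[i] <- b$residues$y[i] + rnorm(40, sd = 0.5)
  b$residues$z[i] <- b$residues$z[i] + rnorm(40, sd = 0.5)
  base <- superpose(a, b)$rmsd
  for (k in 1:5) {
    tr <- list(rotation = random_rotation(), translation = rnorm(3, sd = 10))
    expect_equal(superpose(apply_transform(a, tr), b)$rmsd, base, tolerance = 1e-9)
    expect_equal(superpose(a, apply_transform(b, tr))$rmsd, base, tolerance = 1e-9)
  }
})

test_that("superpose rejects degenerate selections and reports trimming separately", {
  res <- data.frame(chain = "A", resnum = 1:4, resname = "GLY",
                    x = c(0, 1, 2, 3), y = 0, z = 0, has_ca = TRUE)
  lin <- structure_model(res)
  expect_error(superpose(lin, lin), class = "structkit_degenerate-selection")
  two <- structure_model(res[1:2, ])
  expect_error(superpose(two, two), class = "structkit_too-few-pairs")

  # one gross outlier: trimmed rmsd drops, all-atom rmsd is still reported
  a <- make_toy_structure(50, "random-walk", seed = 3)
  b <- a
  b$residues$x[25] <- b$residues$x[25] + 40
  sp <- superpose(a, b, trim = TRUE)
  expect_gt(sp$rmsd, sp$trimmed$rmsd)
  expect_equal(sp$trimmed$n_atoms, 49)
})

test_that("domain assignment matches the published architecture", {
  tab <- rnf213_domains()
  expect_equal(assign_domain(1000, tab), "N-arm")
  expect_equal(assign_domain(2500, tab), "AAA core")
  expect_equal(assign_domain(4753, tab), "E3 module")
  expect_equal(assign_domain(3500, tab), "hinge")
  expect_equal(assign_domain(5000, tab), "CTD")
  expect_equal(assign_domain(3950, tab, level = "subdomain"), "E3-RING")
  expect_equal(assign_domain(6000, tab), "unassigned")
  expect_error(assign_domain(0, tab), class = "structkit_bad-resnum")
})

test_that("assign_domain agrees with a brute-force scan on random residues", {
  tab <- rnf213_domains()
  set.seed(13)
  r <- sample.int(6000, 10000, replace = TRUE)
  for (lv in c("module", "subdomain")) {
    e <- tab[tab$level == lv, ]
    bf <- vapply(r, function(p) {
      hit <- e$name[p >= e$start & p <= e$end]
      if (length(hit)) hit else "unassigned"
    }, character(1))
    expect_identical(assign_domain(r, tab, lv), bf)
  }
})

test_that("validate_domain_table reports gaps and overlaps", {
  tab <- rnf213_domains()
  rep_mod <- validate_domain_table(tab, full_range = c(1, 5148))$module
  expect_equal(nrow(rep_mod$gaps), 0)      # module level tiles 1-5148
  expect_equal(nrow(rep_mod$overlaps), 0)

  bad <- data.frame(name = c("a", "b"), start = c(1L, 5L), end = c(10L, 20L),
                    level = "module")
  rep_bad <- validate_domain_table(bad)$module
  expect_equal(nrow(rep_bad$overlaps), 1)
  expect_error(validate_domain_table(bad, strict = TRUE),
               class = "structkit_overlap")
  expect_error(domain_table(c("a", "b"), c(1, 5), c(10, 20)),
               class = "structkit_overlap")

  hole <- domain_table("mid", 10, 20)
  g <- validate_domain_table(hole, full_range = c(1, 30))$module$gaps
  expect_equal(g$start, c(1, 21))
  expect_equal(g$end, c(9, 30))
})

test_that("domain tables round-trip through TSV", {
  tab <- rnf213_domains()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_domain_table(tab, f)
  expect_equal(as.data.frame(read_domain_table(f)), as.data.frame(tab))
})
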