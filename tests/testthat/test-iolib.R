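test_that("score table reader validates and preserves the fixture", {
  tab <- fixture_docking_scores()
  expect_s3_class(tab, "score_table")
  expect_length(tab$compound_ids, 32L)
  expect_identical(tab$program_names,
                   c("ADT", "iDock", "LeDock", "Qvina", "Smina", "Vina",
                     "PLANTS"))
  i <- match("IMPHY004834", tab$compound_ids)
  j <- match("PLANTS", tab$program_names)
  expect_equal(tab$values[i, j], -32.6407)
  expect_true(all(tab$orientation == "lower_is_better"))
})

test_that("minimal one-compound one-column table reads", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("compound_id,ADT\nX,-5.0", f)
  tab <- read_score_table(f)
  expect_equal(dim(tab$values), c(1L, 1L))
  expect_equal(tab$values[1, 1], -5)
})

test_that("score table write/read round-trips exactly", {
  tab <- fixture_docking_scores()
  f <- withr::local_tempfile(fileext = ".csv")
  write_score_table(tab, f)
  back <- read_score_table(f)
  expect_identical(back$compound_ids, tab$compound_ids)
  expect_identical(back$program_names, tab$program_names)
  expect_equal(back$values, tab$values)
})

test_that("reader errors carry useful coordinates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("compound_id,ADT\nA,-5.0\nA,-6.0", f)
  expect_error(read_score_table(f), "duplicate compound_id: A")
  writeLines("compound_id,ADT\nA,-5.0\nB,oops", f)
  expect_error(read_score_table(f), "row 2.*column 'ADT'")
  writeLines("compound_id,ADT", f)
  expect_error(read_score_table(f), "empty")
})

test_that("unicode minus in source tables is normalized on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,ADT", "A,−7.5"), f)
  expect_equal(read_score_table(f)$values[1, 1], -7.5)
})

test_that("orbital reader validates energies and passes dipoles through", {
  recs <- fixture_orbitals()
  r <- recs[recs$compound_id == "IMPHY003213", ]
  expect_equal(r$E_HOMO, -0.2385)
  expect_equal(r$E_LUMO, -0.1261)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("compound_id,E_HOMO,E_LUMO\nX,-0.1,-0.2", f)
  expect_error(read_orbitals(f), "E_HOMO > E_LUMO")
})

test_that("energy component reader splits plus-minus cells and rejects negative SD", {
  recs <- fixture_mmpbsa()
  r <- recs[recs$compound_id == "IMPHY014076", ]
  expect_equal(r$vdw_mean, -16.120)
  expect_equal(r$vdw_sd, 0.014)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,vdw,elec,polar_solv,sasa",
               "X,−1.5 ± 0.2,2.0 ± 0.1,0.5 ± 0.0,-0.1 ± 0.05"), f)
  pm <- read_energy_components(f)
  expect_equal(pm$vdw_mean, -1.5)
  expect_equal(pm$vdw_sd, 0.2)
  writeLines(c("compound_id,vdw_mean,vdw_sd,elec_mean,elec_sd,polar_solv_mean,polar_solv_sd,sasa_mean,sasa_sd",
               "X,-1,-1,0,0,0,0,0,0"), f)
  expect_error(read_energy_components(f), "negative SD")
  writeLines(c("compound_id,vdw,elec,sasa", "X,1 ± 0,2 ± 0,3 ± 0"), f)
  expect_error(read_energy_components(f), "polar_solv")
})

test_that("vina score extraction takes the first pose", {
  lines <- c("REMARK VINA RESULT:    -7.6   0.000   0.000",
             "REMARK VINA RESULT:    -7.1   1.210   2.002")
  expect_equal(read_vina_pdbqt_score(lines), -7.6)
  expect_error(read_vina_pdbqt_score("ATOM      1  C   UNK A   1"),
               "no score record found")
  expect_error(read_vina_pdbqt_score(character(0)), "no score record")
})

test_that("trajectory readers agree across PDB and XYZ renderings", {
  g <- gen_trajectory(n_atoms = 6, n_frames = 3, sigma = 0.3, seed = 11)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  xyz <- withr::local_tempfile(fileext = ".xyz")
  topf <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_pdb(g$traj, pdb)
  write_trajectory_xyz(g$traj, xyz)
  write_topology(g$traj$topology, topf)
  t_pdb <- read_trajectory(pdb, topf)
  t_xyz <- read_trajectory(xyz, topf)
  expect_equal(dim(t_pdb$coords), dim(g$traj$coords))
  # PDB carries 3 decimals; XYZ is near-exact
  expect_lt(max(abs(t_pdb$coords - t_xyz$coords)), 1e-3)
  expect_lt(max(abs(t_xyz$coords - g$traj$coords)), 1e-7)
})

test_that("bio3d parses the multi-model PDB rendering identically", {
  g <- gen_trajectory(n_atoms = 5, n_frames = 4, sigma = 0.2, seed = 3)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(g$traj, pdb)
  ref <- suppressWarnings(bio3d::read.pdb(pdb, multi = TRUE))
  mine <- read_trajectory(pdb, g$traj$topology)
  for (f in 1:4) {
    theirs <- matrix(ref$xyz[f, ], ncol = 3, byrow = TRUE)
    expect_equal(unname(matrix(mine$coords[f, , ], ncol = 3)), theirs,
                 tolerance = 1e-8)
  }
})

test_that("frame and topology mismatches are rejected with frame index", {
  xyz <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "f1", "C 0 0 0", "C 1 0 0", "C 0 1 0",
               "2", "f2", "C 0 0 0", "C 1 0 0"), xyz)
  expect_error(read_trajectory(xyz, simple_topology(3)), "frame 2")
  xyz2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "f1", "C 0 0 0", "C 1 0 0"), xyz2)
  expect_error(read_trajectory(xyz2, simple_topology(3)),
               "topology covers 3 atoms")
})

test_that("XYZ reader repeats identical frames bitwise", {
  xyz <- withr::local_tempfile(fileext = ".xyz")
  frame <- c("2", "f", "C 1.25 -0.5 3.125", "O 0 0 0")
  writeLines(rep(frame, 5), xyz)
  tr <- read_trajectory(xyz, simple_topology(2))
  expect_equal(dim(tr$coords)[1], 5L)
  for (f in 2:5) expect_identical(tr$coords[f, , ], tr$coords[1, , ])
})

test_that("trajectory constructor enforces time monotonicity", {
  co <- array(0, c(2, 2, 3))
  expect_error(trajectory(co, simple_topology(2), times = c(2, 1)),
               "strictly increasing")
  expect_silent(trajectory(co, simple_topology(2), times = c(1, 2)))
})

test_that("nm-to-Angstrom scaling is applied on request", {
  xyz <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "f", "C 0.1 0.2 0.3"), xyz)
  tr <- read_trajectory(xyz, simple_topology(1), scale = 10)
  expect_equal(as.numeric(tr$coords[1, 1, ]), c(1, 2, 3))
})
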