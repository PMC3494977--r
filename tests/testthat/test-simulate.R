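# Drive-based synthetic data generator and its calibration experiments.

test_that("Yule trees have the requested shape and are seed-reproducible", {
  tr <- simulate_yule_tree(2, seed = 1)
  expect_equal(ape::Ntip(tr), 2L)
  tr <- simulate_yule_tree(25, seed = 2)
  expect_equal(ape::Ntip(tr), 25L)
  expect_true(ape::is.binary(tr))
  expect_true(ape::is.rooted(tr))
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(simulate_yule_tree(25, seed = 2)))
  expect_error(simulate_yule_tree(1), "n_tips")
})

test_that("karyotype evolution conserves autosomal arm number", {
  p <- sim_params(n_tips = 30, rearrange_rate = 3, drive_values = c(-1, 1),
                  seed = 6)
  set.seed(6)
  tr <- simulate_yule_tree(30)
  kev <- evolve_karyotypes(tr, p)
  arms0 <- p$ancestral_acro_pairs + 2 * p$ancestral_biarm_pairs
  expect_true(all(kev$node_A + 2 * kev$node_B == arms0))
  expect_true(all(kev$tip_states$A >= 0 & kev$tip_states$B >= 0))
})

test_that("zero rearrangement rate leaves the ancestral karyotype", {
  p <- sim_params(n_tips = 15, rearrange_rate = 0, seed = 7)
  ds <- simulate_dataset(p)
  expect_true(all(ds$karyo$tip_states$A == p$ancestral_acro_pairs))
  expect_true(all(ds$karyo$tip_states$B == p$ancestral_biarm_pairs))
})

test_that("extreme drive sends karyotypes to the fixable extreme", {
  # strong biarm-favoring drive: every fusion fixes, no fission does
  p <- sim_params(n_tips = 15, rearrange_rate = 40, drive_values = c(50, 50),
                  ancestral_acro_pairs = 20, ancestral_biarm_pairs = 0,
                  sex_fusion_rate = 0, seed = 8)
  ds <- simulate_dataset(p)
  frac <- with(ds$karyo$tip_states, A / (A + B))
  expect_true(all(frac <= 2 / 20))   # at most one unfusable acrocentric left
  # mirrored acro-favoring drive: only fissions fix, so B is non-increasing;
  # the last fissions get rare because fusion proposals dominate at high A,
  # so the fraction approaches 1 without demanding B = 0 exactly
  p2 <- sim_params(n_tips = 15, rearrange_rate = 120, drive_values = c(-50, -50),
                   ancestral_acro_pairs = 0, ancestral_biarm_pairs = 10,
                   sex_fusion_rate = 0, seed = 9)
  ds2 <- simulate_dataset(p2)
  frac2 <- with(ds2$karyo$tip_states, A / (A + B))
  expect_true(all(ds2$karyo$tip_states$B < 10))
  expect_true(all(frac2 > 0.6))
})

test_that("sex system assignment obeys its limiting cases", {
  p <- sim_params(n_tips = 20, sex_fusion_rate = 0, seed = 10)
  ds <- simulate_dataset(p)
  expect_true(all(ds$systems == "simple"))
  expect_equal(nrow(ds$records), 0L)

  # X fusions cannot fix under strongly acro-favoring drive
  p2 <- sim_params(n_tips = 40, sex_fusion_rate = 3, rearrange_rate = 0,
                   drive_values = c(-40, -40), seed = 11)
  ds2 <- simulate_dataset(p2)
  expect_false(any(ds2$systems == "XY1Y2"))
  expect_gt(sum(ds2$systems == "X1X2Y"), 0)

  # no acrocentric autosomes: the sex-fusion rate factor is zero
  p3 <- sim_params(n_tips = 20, sex_fusion_rate = 5, rearrange_rate = 0,
                   ancestral_acro_pairs = 0, ancestral_biarm_pairs = 8,
                   seed = 12)
  ds3 <- simulate_dataset(p3)
  expect_true(all(ds3$systems == "simple"))
})

test_that("emitted datasets reload under strict validation", {
  p <- sim_params(n_tips = 40, sex_fusion_rate = 1, seed = 13)
  ds <- simulate_dataset(p)
  expect_gt(nrow(ds$records), 0)
  dir <- withr::local_tempdir()
  paths <- emit_dataset(ds$tree, ds$karyo, ds$systems, dir, params = p)
  reloaded <- load_karyotype_table(paths[["table"]], quiet = TRUE)
  expect_true(all(reloaded$valid))
  expect_equal(as.data.frame(reloaded), as.data.frame(ds$records))
  # fractions equal the count-based fraction exactly
  st <- ds$karyo$tip_states
  st_sys <- st[match(ds$records$genus, sub("_.*$", "", st$label)), ]
  expect_equal(ds$records$female_frac_acro,
               acrocentric_fraction_from_counts(pmax(st_sys$A - 1, 0),
                                                st_sys$B))
  # truth file keeps the simple tips the table excludes
  truth <- jsonlite::fromJSON(paths[["truth"]])
  expect_equal(nrow(truth$tips), ape::Ntip(ds$tree))

  # seeded rerun emits byte-identical files
  ds2 <- simulate_dataset(p)
  dir2 <- withr::local_tempdir()
  paths2 <- emit_dataset(ds2$tree, ds2$karyo, ds2$systems, dir2, params = p)
  for (nm in names(paths))
    expect_identical(readLines(paths[[nm]]), readLines(paths2[[nm]]))
})

test_that("a strong drive mixture induces a bimodal fraction distribution", {
  pooled <- function(d_val, seed0) {
    out <- numeric(0)
    for (i in 1:20) {
      p <- sim_params(n_tips = 48, rearrange_rate = 24,
                      drive_values = c(-d_val, d_val),
                      drive_switch_rate = 0.1, sex_fusion_rate = 0,
                      seed = seed0 + i)
      st <- simulate_dataset(p)$karyo$tip_states
      out <- c(out, st$A / (st$A + st$B))
    }
    out
  }
  fr_drive <- pooled(4, 100)
  fr_null <- pooled(0, 200)
  bins <- function(x) tabulate(pmin(floor(x / 0.1), 9) + 1L, 10L) / length(x)
  bd <- bins(fr_drive)
  # two modes with a dip between them
  lo_mode <- which.max(bd[1:5])
  hi_mode <- 5 + which.max(bd[6:10])
  dip <- min(bd[lo_mode:hi_mode])
  expect_gt(bd[lo_mode], 3 * dip)
  expect_gt(bd[hi_mode], 3 * dip)
  # the neutral control is unimodal: no interior dip of that depth
  bn <- bins(fr_null)
  lo_n <- which.max(bn[1:5])
  hi_n <- 5 + which.max(bn[6:10])
  dip_n <- min(bn[lo_n:hi_n])
  expect_false(bn[lo_n] > 3 * dip_n && bn[hi_n] > 3 * dip_n)
})

test_that("experiment guards reject ill-posed configurations", {
  p_drive <- sim_params(drive_values = c(-1, 1))
  expect_error(type_i_error_experiment(p_drive, reps = 10), "zero drive")
  p_null <- sim_params(n_tips = 40, sex_fusion_rate = 1)
  # alpha boundaries are trivially calibrated
  expect_equal(type_i_error_experiment(p_null, reps = 5, alpha = 1,
                                       seed = 1)$rate, 1)
  expect_equal(type_i_error_experiment(p_null, reps = 5, alpha = 0,
                                       seed = 1)$rate, 0)
  r1 <- sign_recovery_experiment(p_null, reps = 1, seed = 2)
  expect_true(r1$recovery %in% c(0, 0.5, 1))
})

test_that("simulated clusters pass an independent monophyly check", {
  set.seed(30)
  p <- sim_params(n_tips = 80, sex_fusion_rate = 0.6)
  p$seed <- NULL
  for (i in 1:5) {
    ds <- karyopairs:::kp_sim_until_informative(p)
    rec <- ds$records
    units <- find_system_clusters(ds$analysis_tree,
                                  stats::setNames(rec$system, rec$species_key))
    for (u in units) {
      if (length(u$members) > 1) {
        clade <- ape::extract.clade(ds$analysis_tree,
                                    ape::getMRCA(ds$analysis_tree, u$members))
        expect_setequal(clade$tip.label, u$members)
      }
      expect_equal(unique(rec$system[match(u$members, rec$species_key)]),
                   u$system)
    }
  }
})
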