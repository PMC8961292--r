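toy_complex_pdb <- function(seed = 8) {
  tc <- make_toy_pocket_complex(seed = seed)
  f <- tempfile(fileext = ".pdb")
  write_minipdb(tc$model, f)
  list(path = f, truth = tc$truth)
}

test_that("the EH-domain contact recipe reproduces the direct computation", {
  fx <- toy_complex_pdb()
  on.exit(unlink(fx$path))
  cfg <- recipe_config("fig3_contacts",
                       inputs = list(TOY = fx$path),
                       chains = list(eh2 = c("A", "B"), peptide = "P"),
                       options = list(npf_resnos = 1:3, keep_hydrogens = FALSE))
  rep <- run_recipe(cfg)
  m <- read_structure(fx$path)
  direct <- interchain_contacts(m, selection(m, chain = c("A", "B")),
                                selection(m, chain = "P", resno = 1:3))
  expect_equal(rep$tables$contacts, direct$records)
  expect_equal(rep$tables$residue_pairs, direct$pair_summary)
})

test_that("the distance recipe measures the NPF proline to cysteine span", {
  atoms <- rbind(
    atom_row("G", 63, "PRO", "CA", -1.5, 0, 0),
    atom_row("G", 63, "PRO", "CB", 0, 0, 0),
    atom_row("G", 63, "PRO", "CG", -0.4, 1.2, 0),
    atom_row("R", 316, "CYS", "CA", 40.0, 0, 0),
    atom_row("R", 316, "CYS", "SG", 41.2, 1.0, 0, element = "S"))
  m <- structure_model(atoms, "syn_complex")
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f))
  write_minipdb(m, f)
  cfg <- recipe_config("fig7_distance",
                       inputs = list(SYN = f),
                       chains = list(ggamma = "G", receptor = "R"))
  rep <- run_recipe(cfg)
  expect_equal(rep$tables$distance$min_distance, 40, tolerance = 1e-3)
  expect_equal(rep$tables$distance$receptor_cys_resno, 316)
})

test_that("recipes are deterministic and reports regenerate byte-identically", {
  fx <- toy_complex_pdb(seed = 12)
  on.exit(unlink(fx$path))
  cfg <- recipe_config("fig3_contacts",
                       inputs = list(TOY = fx$path),
                       chains = list(eh2 = c("A", "B"), peptide = "P"),
                       options = list(npf_resnos = 1:3, keep_hydrogens = FALSE))
  r1 <- run_recipe(cfg)
  r2 <- run_recipe(cfg)
  expect_identical(r1$tables, r2$tables)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  write_report(r1, d1); write_report(r2, d2)
  t1 <- file.path(d1, "fig3_contacts_contacts.tsv")
  t2 <- file.path(d2, "fig3_contacts_contacts.tsv")
  expect_identical(readLines(t1), readLines(t2))
})

test_that("missing inputs are reported with accession and role, never fetched", {
  cfg <- recipe_config("fig7_distance",
                       inputs = list(`6QNO` = file.path(tempdir(), "absent.pdb")),
                       chains = list(ggamma = "G", receptor = "R"))
  expect_error(run_recipe(cfg), "6QNO.*receptor-G protein complex|not found")
  cfg2 <- recipe_config("fig3_contacts", inputs = list(`1F8H` = "also_absent.pdb"),
                        chains = list(eh2 = "A", peptide = "P"))
  expect_error(run_recipe(cfg2), "1F8H")
})

test_that("recipe configurations round-trip through YAML", {
  y <- tempfile(fileext = ".yml")
  on.exit(unlink(y))
  writeLines(c(
    "recipe: fig7_distance",
    "inputs:",
    "  6QNO: /data/6qno.pdb",
    "chains:",
    "  ggamma: G",
    "  receptor: R",
    "options:",
    "  cutoff: 4.0",
    "  pro_resno: 63"), y)
  cfg <- read_recipe_config(y)
  expect_s3_class(cfg, "recipe_config")
  expect_equal(cfg$recipe, "fig7_distance")
  expect_equal(cfg$inputs[["6QNO"]], "/data/6qno.pdb")
  expect_equal(cfg$options$pro_resno, 63)
})

test_that("the persistence recipe flags displaced conformations", {
  tc <- make_toy_pocket_complex(seed = 20)
  f_r <- tempfile(fileext = ".pdb"); f_t <- tempfile(fileext = ".pdb")
  on.exit(unlink(c(f_r, f_t)))
  write_minipdb(tc$model, f_r)
  moved <- tc$model$atoms
  moved[moved$chain == "P", c("x", "y", "z")] <-
    moved[moved$chain == "P", c("x", "y", "z")] + 10
  write_minipdb(structure_model(moved, "tstate"), f_t)
  cfg <- recipe_config("fig10_states",
                       inputs = list(RSTATE = f_r, TSTATE = f_t),
                       chains = list(receptor = "A", gbeta = "P"),
                       options = list(ctail_resnos = 1:18,
                                      gbeta_resnos = 1:3))
  rep <- run_recipe(cfg)
  expect_gt(nrow(rep$tables$rstate_contacts), 0)
  expect_true(all(rep$tables$tstate_persistence$broken))
})
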