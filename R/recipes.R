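# Named analysis recipes.
#
# Each recipe reproduces one published table or measurement from
# user-supplied coordinate files: inter-chain contact lists for the
# EH-domain/peptide complexes, the receptor C-tail self-contacts, the dimer
# interface, the R/T-state contact-persistence comparison, the NPF-proline to
# Cys316 distance and the H8 rotation angle. Inputs are never downloaded:
# a missing file is an error naming the accession and its role.
#
# Chain roles (which chain is the receptor, Gbeta, Ggamma, EH domain,
# peptide) are declared in the config per accession, because chain lettering
# varies between depositions.

RECIPE_NAMES <- c("fig3_contacts", "fig5_compare", "fig6_overlap",
                  "fig7_distance", "fig8_ctail", "fig9_dimer", "fig10_states")

#' Build a recipe configuration
#'
#' @param recipe recipe name, one of `npfsite_recipes()`.
#' @param inputs named list: accession -> file path.
#' @param chains named list: role -> chain id (roles depend on the recipe,
#'   e.g. `eh2`, `peptide`, `receptor`, `gbeta`, `ggamma`, `protomer_a`,
#'   `protomer_b`, `alt_gbeta`).
#' @param options named list: `cutoff` (default 4), `keep_hydrogens`
#'   (default follows the hydrogen policy of the deposition being analysed),
#'   `model_index` (default 1), plus recipe-specific residue numbers.
#' @return list of class `recipe_config`.
#' @export
recipe_config <- function(recipe, inputs, chains = list(), options = list()) {
  recipe <- match.arg(recipe, RECIPE_NAMES)
  stopifnot(is.list(inputs), length(inputs) > 0, !is.null(names(inputs)))
  structure(list(recipe = recipe, inputs = inputs, chains = chains,
                 options = options),
            class = "recipe_config")
}

#' Recipe names known to the package
#' @return character vector.
#' @export
npfsite_recipes <- function() RECIPE_NAMES

#' Read a recipe configuration from a YAML file
#' @param path YAML file with keys `recipe`, `inputs`, `chains`, `options`.
#' @return a [recipe_config()].
#' @export
read_recipe_config <- function(path) {
  y <- yaml::read_yaml(path)
  recipe_config(y$recipe, y$inputs, y$chains %||% list(), y$options %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

recipe_input <- function(config, accession, role) {
  path <- config$inputs[[accession]]
  if (is.null(path))
    stop("recipe ", config$recipe, " needs an input for accession ", accession,
         " (role: ", role, ")")
  if (!file.exists(path))
    stop("input file for accession ", accession, " (role: ", role,
         ") not found: ", path)
  path
}

recipe_chain <- function(config, role, default = NULL) {
  ch <- config$chains[[role]]
  if (is.null(ch)) {
    if (is.null(default)) stop("recipe ", config$recipe,
                               " needs a chain declared for role '", role, "'")
    ch <- default
  }
  ch
}

#' Run a named analysis recipe
#'
#' @param config a [recipe_config()].
#' @return object of class `recipe_report`: `recipe`, `inputs` (paths and
#'   md5 checksums), `parameters`, `tables` (named list of data.frames) and
#'   `log`. Re-running with identical inputs yields identical tables.
#' @export
run_recipe <- function(config) {
  stopifnot(inherits(config, "recipe_config"))
  opts <- config$options
  cutoff <- opts$cutoff %||% 4.0
  model_index <- opts$model_index %||% 1L
  logline <- character(0)
  note <- function(...) logline <<- c(logline, sprintf(...))

  load_input <- function(accession, role, keep_h) {
    path <- recipe_input(config, accession, role)
    m <- read_structure(path, model_index = model_index, keep_hydrogens = keep_h)
    note("loaded %s (%s) from %s: model %d, hydrogens %s",
         accession, role, path, model_index, if (keep_h) "kept" else "stripped")
    m
  }

  tables <- switch(
    config$recipe,
    fig3_contacts = {
      # EH-domain helices vs the NPF tripeptide of the bound peptide;
      # the deposition carries hydrogens, so they are kept by default
      keep_h <- opts$keep_hydrogens %||% TRUE
      m <- load_input(names(config$inputs)[1], "eh2+peptide complex", keep_h)
      eh2_chain <- recipe_chain(config, "eh2")
      pep_chain <- recipe_chain(config, "peptide")
      npf <- opts$npf_resnos
      pep_sel <- selection(m, chain = pep_chain, resno = npf)
      ct <- interchain_contacts(m, selection(m, chain = eh2_chain), pep_sel,
                                cutoff = cutoff)
      note("contacts: %d atom pairs < %.2f A", nrow(ct$records), cutoff)
      list(contacts = ct$records, residue_pairs = ct$pair_summary)
    },
    fig5_compare = {
      # contacts of the residues flanking the NPF motif, in two depositions
      keep_h <- opts$keep_hydrogens %||% TRUE
      out <- list()
      for (accession in names(config$inputs)) {
        m <- load_input(accession, "eh2+peptide complex", keep_h)
        eh2_chain <- recipe_chain(config, "eh2")
        pep_chain <- recipe_chain(config, "peptide")
        flank <- opts$flank_resnos
        ct <- interchain_contacts(m, selection(m, chain = eh2_chain),
                                  selection(m, chain = pep_chain, resno = flank),
                                  cutoff = cutoff)
        out[[paste0(accession, "_pairs")]] <- ct$pair_summary
      }
      out
    },
    fig6_overlap = {
      # EH-domain SLE contacts to the peptide vs receptor NKQ contacts to
      # the G-alpha C-terminal helix
      keep_h_eh <- opts$keep_hydrogens %||% TRUE
      acc <- names(config$inputs)
      m_eh <- load_input(acc[1], "eh2+peptide complex", keep_h_eh)
      m_r <- load_input(acc[2], "receptor + Galpha peptide", FALSE)
      sle <- opts$sle_resnos %||% c(53L, 54L, 55L)
      nkq <- opts$nkq_resnos %||% c(310L, 311L, 312L)
      eh_ct <- interchain_contacts(
        m_eh, selection(m_eh, chain = recipe_chain(config, "eh2"), resno = sle),
        selection(m_eh, chain = recipe_chain(config, "peptide")), cutoff = cutoff)
      r_ct <- interchain_contacts(
        m_r, selection(m_r, chain = recipe_chain(config, "receptor"), resno = nkq),
        selection(m_r, chain = recipe_chain(config, "galpha_peptide")),
        cutoff = cutoff)
      list(sle_peptide_pairs = eh_ct$pair_summary,
           nkq_galpha_pairs = r_ct$pair_summary)
    },
    fig7_distance = {
      # NPF-proline side chain of Ggamma vs receptor Cys316
      m <- load_input(names(config$inputs)[1], "receptor-G protein complex",
                      opts$keep_hydrogens %||% FALSE)
      pro <- opts$pro_resno %||% 63L
      cys <- opts$cys_resno %||% 316L
      d <- min_distance(
        selection(m, chain = recipe_chain(config, "ggamma"), resno = pro,
                  sidechain_only = TRUE),
        selection(m, chain = recipe_chain(config, "receptor"), resno = cys))
      note("NPF proline (resno %d) to Cys%d minimum distance: %.2f A", pro, cys, d)
      list(distance = data.frame(ggamma_pro_resno = pro, receptor_cys_resno = cys,
                                 min_distance = d))
    },
    fig8_ctail = {
      # receptor C-tail against its own TM1/ICL1/H8, plus PIC-style types
      m <- load_input(names(config$inputs)[1], "receptor",
                      opts$keep_hydrogens %||% FALSE)
      rc <- recipe_chain(config, "receptor")
      ctail <- opts$ctail_resnos %||% 335:345
      site <- opts$site_resnos %||% c(35:64, 65:70, 310:321)
      ct <- interchain_contacts(m, selection(m, chain = rc, resno = ctail),
                                selection(m, chain = rc, resno = site),
                                cutoff = cutoff)
      ints <- intrachain_interactions(m, rc, ranges = sort(unique(c(ctail, site))))
      list(ctail_contacts = ct$records, ctail_pairs = ct$pair_summary,
           interaction_types = ints)
    },
    fig9_dimer = {
      # contacts across the two protomers of a receptor dimer
      keep_h <- opts$keep_hydrogens %||% TRUE
      m <- load_input(names(config$inputs)[1], "receptor dimer", keep_h)
      ct <- interchain_contacts(
        m, selection(m, chain = recipe_chain(config, "protomer_a")),
        selection(m, chain = recipe_chain(config, "protomer_b")), cutoff = cutoff)
      list(interface_contacts = ct$records, interface_pairs = ct$pair_summary)
    },
    fig10_states = {
      # contacts seen in the receptor-bound (R-state) complex, re-evaluated
      # in an alternative (T-state) conformation of Gbetagamma
      acc <- names(config$inputs)
      m_r <- load_input(acc[1], "receptor-G protein complex (R-state)",
                        opts$keep_hydrogens %||% FALSE)
      m_t <- load_input(acc[2], "alternative Gbetagamma conformation (T-state)",
                        opts$keep_hydrogens %||% FALSE)
      ctail <- opts$ctail_resnos %||% 325:348
      gb_res <- opts$gbeta_resnos %||% c(271L, 290L, 291L, 314L)
      ct <- interchain_contacts(
        m_r, selection(m_r, chain = recipe_chain(config, "receptor"), resno = ctail),
        selection(m_r, chain = recipe_chain(config, "gbeta"), resno = gb_res),
        cutoff = cutoff)
      mapping <- opts$chain_mapping
      persist <- contact_persistence(swap_contact_sides(ct), m_t, mapping = mapping)
      list(rstate_contacts = ct$pair_summary, tstate_persistence = persist)
    }
  )
  inputs_df <- data.frame(
    accession = names(config$inputs),
    path = unlist(config$inputs, use.names = FALSE),
    md5 = vapply(unlist(config$inputs, use.names = FALSE), function(p)
      if (file.exists(p)) as.character(tools::md5sum(p)) else NA_character_,
      character(1)),
    stringsAsFactors = FALSE)
  structure(list(recipe = config$recipe, inputs = inputs_df,
                 parameters = c(list(cutoff = cutoff, model_index = model_index),
                                config$options),
                 tables = tables, log = logline),
            class = "recipe_report")
}

# contact_persistence maps the *a* side then the *b* side; recipes that
# persist the Gbeta side need the table with Gbeta residues in column a
swap_contact_sides <- function(ct) {
  r <- ct$records
  swapped <- data.frame(residue_a = r$residue_b, resname_a = r$resname_b,
                        atom_a = r$atom_b, residue_b = r$residue_a,
                        resname_b = r$resname_a, atom_b = r$atom_a,
                        distance = r$distance,
                        involves_hydrogen = r$involves_hydrogen,
                        stringsAsFactors = FALSE)
  new_contact_table(swapped, ct$cutoff)
}

#' @export
print.recipe_report <- function(x, ...) {
  cat(sprintf("recipe_report '%s': %d table(s)\n", x$recipe, length(x$tables)))
  for (nm in names(x$tables))
    cat(sprintf("  %s: %d row(s)\n", nm, nrow(x$tables[[nm]])))
  invisible(x)
}

#' Write a recipe report to disk
#'
#' One TSV per table plus a JSON sidecar with inputs, checksums, parameters
#' and the run log, so a report plus the package version regenerates itself.
#'
#' @param report a `recipe_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "recipe_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(report$tables)) {
    p <- file.path(dir, paste0(report$recipe, "_", nm, ".tsv"))
    write.table(report$tables[[nm]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- list(recipe = report$recipe, inputs = report$inputs,
               parameters = report$parameters, log = report$log)
  p <- file.path(dir, paste0(report$recipe, "_report.json"))
  jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, p))
}
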