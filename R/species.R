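#' Species catalog for the full polarity model
#'
#' Builds the roster of the 39 state fields of the model: monomeric and
#' polymeric forms of the three scaffolding proteins (PopZ, the long and
#' short forms of PodJ, and SpmX), the protease PerP, and the signaling
#' proteins of the DivJ/PleC-DivK and DivL-CckA-CpdR/CtrA phosphorelay
#' modules. Signaling proteins that are recruited to the poles carry a
#' cytosolic (`layer = "cyto"`) and a polar-membrane-bound
#' (`layer = "membrane"`, suffix `_b`) form; the bound forms diffuse
#' slowly and exchange with the cytosolic pool at a rate enhanced by the
#' local concentration of the recruiting scaffold polymer.
#'
#' @param full logical; if `FALSE`, return only the two-field PopZ
#'   activator-substrate subsystem (used for isolated Turing-pattern runs).
#' @return A data frame of class `caulo_catalog` with one row per state
#'   field and columns `name`, `family`, `form` (one of `monomer`,
#'   `polymer`, `phospho`, `complex`, `plain`), `layer`, `mw` (kDa, for
#'   species whose diffusivity follows the empirical mass law; `NA` for
#'   polymers and membrane-bound forms), `gene` (locus whose synthesis
#'   feeds the species, or `NA`), and `partners` (`;`-separated for
#'   complexes).
#' @export
#' @examples
#' cat39 <- species_catalog()
#' nrow(cat39)  # 39 state fields
species_catalog <- function(full = TRUE) {
  sp <- function(name, family, form, layer = "cyto", mw = NA_real_,
                 gene = NA_character_, partners = NA_character_) {
    data.frame(name = name, family = family, form = form, layer = layer,
               mw = mw, gene = gene, partners = partners,
               stringsAsFactors = FALSE)
  }
  rows <- list(
    ## scaffolding proteins: activator-substrate-depletion pairs
    sp("PopZ_m",  "PopZ",  "monomer", mw = 19.2, gene = "popZ"),
    sp("PopZ_p",  "PopZ",  "polymer"),
    sp("PodJL_m", "PodJL", "monomer", mw = 102,  gene = "podJ"),
    sp("PodJL_p", "PodJL", "polymer"),
    sp("PodJS_m", "PodJS", "monomer", mw = 85),
    sp("PodJS_p", "PodJS", "polymer"),
    sp("SpmX_m",  "SpmX",  "monomer", mw = 46.5, gene = "spmX"),
    sp("SpmX_p",  "SpmX",  "polymer"),
    ## PerP protease (truncates PodJL into PodJS)
    sp("PerP",    "PerP",  "plain",   mw = 24,   gene = "perP"),
    ## DivK response regulator
    sp("DivK",    "DivK",  "plain",   mw = 14,   gene = "divK"),
    sp("DivKp",   "DivK",  "phospho", mw = 14),
    sp("DivK_b",  "DivK",  "plain",   layer = "membrane"),
    sp("DivKp_b", "DivK",  "phospho", layer = "membrane"),
    ## DivJ kinase and its DivK complexes
    sp("DivJ",         "DivJ", "plain",   mw = 66, gene = "divJ"),
    sp("DivJ_b",       "DivJ", "plain",   layer = "membrane"),
    sp("DivJ_DivK",    "DivJ", "complex", mw = 80, partners = "DivJ;DivK"),
    sp("DivJ_DivK_b",  "DivJ", "complex", layer = "membrane", partners = "DivJ;DivK"),
    sp("DivJ_DivKp",   "DivJ", "complex", mw = 80, partners = "DivJ;DivKp"),
    sp("DivJ_DivKp_b", "DivJ", "complex", layer = "membrane", partners = "DivJ;DivKp"),
    ## PleC bifunctional kinase/phosphatase
    sp("PleC_ph",      "PleC", "plain",   mw = 92, gene = "pleC"),
    sp("PleC_ph_b",    "PleC", "plain",   layer = "membrane"),
    sp("PleC_kin",     "PleC", "plain",   mw = 92),
    sp("PleC_kin_b",   "PleC", "plain",   layer = "membrane"),
    sp("PleC_DivKp",   "PleC", "complex", mw = 106, partners = "PleC_ph;DivKp"),
    sp("PleC_DivKp_b", "PleC", "complex", layer = "membrane", partners = "PleC_ph;DivKp"),
    ## DivL pseudokinase
    sp("DivL",         "DivL", "plain",   mw = 85, gene = "divL"),
    sp("DivL_b",       "DivL", "plain",   layer = "membrane"),
    sp("DivL_DivKp",   "DivL", "complex", mw = 99, partners = "DivL;DivKp"),
    sp("DivL_DivKp_b", "DivL", "complex", layer = "membrane", partners = "DivL;DivKp"),
    ## CckA bifunctional kinase/phosphatase
    sp("CckA_kin",   "CckA", "plain", mw = 76, gene = "cckA"),
    sp("CckA_kin_b", "CckA", "plain", layer = "membrane"),
    sp("CckA_ph",    "CckA", "plain", mw = 76),
    sp("CckA_ph_b",  "CckA", "plain", layer = "membrane"),
    ## CpdR proteolysis adaptor
    sp("CpdR_u",   "CpdR", "plain",   mw = 25, gene = "cpdR"),
    sp("CpdR_u_b", "CpdR", "plain",   layer = "membrane"),
    sp("CpdRp",    "CpdR", "phospho", mw = 25),
    sp("CpdRp_b",  "CpdR", "phospho", layer = "membrane"),
    ## CtrA master regulator
    sp("CtrA_u", "CtrA", "plain",   mw = 26, gene = "ctrA"),
    sp("CtrAp",  "CtrA", "phospho", mw = 26)
  )
  cat <- do.call(rbind, rows)
  if (!full) cat <- cat[cat$name %in% c("PopZ_m", "PopZ_p"), , drop = FALSE]
  rownames(cat) <- cat$name
  class(cat) <- c("caulo_catalog", "data.frame")
  cat
}

#' Validate a species catalog
#'
#' Checks the structural invariants of a [species_catalog()]: unique names,
#' positive molecular weights on monomeric forms, at least two partners on
#' every complex, and (for the full model) a state dimension of 39.
#'
#' @param cat a catalog data frame.
#' @param full logical; enforce the 39-species dimension of the full model.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_catalog <- function(cat, full = TRUE) {
  stopifnot(is.data.frame(cat))
  if (anyDuplicated(cat$name) > 0L) stop("species names must be unique")
  mono <- cat$form == "monomer"
  if (any(!is.finite(cat$mw[mono]) | cat$mw[mono] <= 0))
    stop("every monomer must have a positive molecular weight")
  cx <- cat[cat$form == "complex", ]
  if (nrow(cx) > 0) {
    np <- vapply(strsplit(cx$partners, ";", fixed = TRUE), length, 1L)
    if (any(is.na(cx$partners)) || any(np < 2L))
      stop("every complex must list at least 2 partner species")
  }
  if (full && nrow(cat) != 39L)
    stop("full model catalog must have exactly 39 entries, got ", nrow(cat))
  invisible(TRUE)
}

## Internal constants used by the right-hand side: species that aggregate
## into a protein family total (all phospho-states, complexes, layers).
.family_members <- function(cat, family) cat$name[cat$family == family]

## Total DivK~P (free, membrane-bound, and complexed) -- the quantity
## plotted in the mutant comparisons.
.divkp_species <- c("DivKp", "DivKp_b", "DivJ_DivKp", "DivJ_DivKp_b",
                    "PleC_DivKp", "PleC_DivKp_b", "DivL_DivKp", "DivL_DivKp_b")

## Convenience totals used for exported summaries.
.totals_map <- list(
  PopZ   = c("PopZ_m", "PopZ_p"),
  PodJL  = c("PodJL_m", "PodJL_p"),
  PodJS  = c("PodJS_m", "PodJS_p"),
  PodJ   = c("PodJL_m", "PodJL_p", "PodJS_m", "PodJS_p"),
  SpmX   = c("SpmX_m", "SpmX_p"),
  DivJ   = c("DivJ", "DivJ_b", "DivJ_DivK", "DivJ_DivK_b",
             "DivJ_DivKp", "DivJ_DivKp_b"),
  PleC   = c("PleC_ph", "PleC_ph_b", "PleC_kin", "PleC_kin_b",
             "PleC_DivKp", "PleC_DivKp_b"),
  DivL   = c("DivL", "DivL_b", "DivL_DivKp", "DivL_DivKp_b"),
  CckA   = c("CckA_kin", "CckA_kin_b", "CckA_ph", "CckA_ph_b"),
  DivK   = c("DivK", "DivK_b", "DivKp", "DivKp_b", "DivJ_DivK",
             "DivJ_DivK_b", "DivJ_DivKp", "DivJ_DivKp_b", "PleC_DivKp",
             "PleC_DivKp_b", "DivL_DivKp", "DivL_DivKp_b"),
  DivKp  = .divkp_species,
  CpdR   = c("CpdR_u", "CpdR_u_b", "CpdRp", "CpdRp_b"),
  CpdR_u = c("CpdR_u", "CpdR_u_b"),
  CtrA   = c("CtrA_u", "CtrAp"),
  CtrAp  = "CtrAp"
)
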