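# Cleavable cross-linker chemistry: arm fragments, doublet deltas,
# alternative cleavage products.

#' Construct a cross-linker arm fragment
#'
#' One of the two remnant fragments that an MS-cleavable cross-linker leaves
#' on a peptide after gas-phase cleavage. The "short" (light) arm is the
#' lighter remnant, the "long" (heavy) arm the heavier one; their mass
#' difference is the doublet delta observed in MS2 spectra.
#'
#' @param label `"short"` or `"long"`.
#' @param composition Elemental formula of the remnant, or `NA` if only the
#'   mass is known.
#' @param mono_mass Monoisotopic mass in Da; computed from `composition` when
#'   omitted. When both are given they must agree within 1e-4 Da.
#' @return An object of class `arm_fragment`.
#' @export
arm_fragment <- function(label, composition = NA_character_, mono_mass = NULL) {
  label <- match.arg(label, c("short", "long"))
  if (is.null(mono_mass)) {
    if (is.na(composition)) stop("arm fragment needs a composition or a mass")
    mono_mass <- mass_from_composition(composition)
  } else if (!is.na(composition)) {
    computed <- mass_from_composition(composition)
    if (abs(computed - mono_mass) > 1e-4) {
      stop(sprintf("arm '%s': stated mass %.5f disagrees with composition %s (%.5f)",
                   label, mono_mass, composition, computed))
    }
  }
  structure(list(label = label, composition = composition,
                 mono_mass = mono_mass),
            class = "arm_fragment")
}

#' Construct a cleavable cross-linker specification
#'
#' @param name Cross-linker name.
#' @param reactive_residues Character vector of reactive amino-acid letters
#'   (e.g. `"K"` for NHS-ester linkers).
#' @param protein_nterm_reactive Whether protein N-termini are reactive.
#' @param short_arm,long_arm [arm_fragment()] objects; the long arm must be
#'   heavier than the short arm.
#' @param products Data frame of alternative cleavage products / losses with
#'   columns `label`, `delta_mass` (signed Da, |delta| < 500) and
#'   `applies_to` (`"short"`, `"long"` or `"both"`). May be empty.
#' @param intact_mass Mass added by the intact (uncleaved) cross-link, used
#'   for precursor-sum consistency checks.
#' @return An object of class `crosslinker_spec`.
#' @seealso [crosslinker()] for the built-in DSSO and DSBSO definitions.
#' @export
crosslinker_spec <- function(name, reactive_residues, protein_nterm_reactive,
                             short_arm, long_arm,
                             products = empty_products(), intact_mass) {
  stopifnot(inherits(short_arm, "arm_fragment"), inherits(long_arm, "arm_fragment"))
  if (length(reactive_residues) == 0L) {
    stop("cross-linker must have at least one reactive residue")
  }
  if (!(long_arm$mono_mass > short_arm$mono_mass)) {
    stop("long arm must be heavier than short arm (doublet delta must be > 0)")
  }
  products <- as.data.frame(products)
  if (nrow(products)) {
    stopifnot(all(c("label", "delta_mass", "applies_to") %in% names(products)))
    if (any(abs(products$delta_mass) >= 500)) {
      stop("cross-linker product |delta_mass| must be < 500 Da")
    }
    if (!all(products$applies_to %in% c("short", "long", "both"))) {
      stop("product applies_to must be one of 'short', 'long', 'both'")
    }
  }
  structure(list(name = name,
                 reactive_residues = sort(unique(reactive_residues)),
                 protein_nterm_reactive = isTRUE(protein_nterm_reactive),
                 short_arm = short_arm, long_arm = long_arm,
                 products = products, intact_mass = intact_mass),
            class = "crosslinker_spec")
}

empty_products <- function() {
  data.frame(label = character(), delta_mass = numeric(),
             applies_to = character(), stringsAsFactors = FALSE)
}

#' @export
print.crosslinker_spec <- function(x, ...) {
  cat(sprintf("<crosslinker_spec> %s\n", x$name))
  cat(sprintf("  reactive: %s%s\n", paste(x$reactive_residues, collapse = ","),
              if (x$protein_nterm_reactive) " + protein N-terminus" else ""))
  cat(sprintf("  short arm: %s (%.5f Da)\n", x$short_arm$composition, x$short_arm$mono_mass))
  cat(sprintf("  long  arm: %s (%.5f Da)\n", x$long_arm$composition, x$long_arm$mono_mass))
  cat(sprintf("  doublet delta: %.5f Da; intact: %.5f Da; %d product(s)\n",
              doublet_delta(x), x$intact_mass, nrow(x$products)))
  invisible(x)
}

#' Doublet mass difference of a cleavable cross-linker
#'
#' The cross-linker-specific mass difference between the heavy- and light-arm
#' remnant peaks of one peptide (31.9721 Da for DSSO, 182.0071 Da for DSBSO).
#'
#' @param spec A [crosslinker_spec()].
#' @return Mass difference in Da (always > 0).
#' @export
doublet_delta <- function(spec) {
  stopifnot(inherits(spec, "crosslinker_spec"))
  spec$long_arm$mono_mass - spec$short_arm$mono_mass
}

#' Arm mass by light/heavy role
#' @param spec A [crosslinker_spec()].
#' @param arm `"light"` (short arm) or `"heavy"` (long arm).
#' @return Monoisotopic arm mass in Da.
#' @export
arm_mass <- function(spec, arm) {
  arm <- match.arg(arm, c("light", "heavy"))
  if (arm == "light") spec$short_arm$mono_mass else spec$long_arm$mono_mass
}

# Built-in chemistries.
#
# DSSO cleaves at either C-S bond of its central sulfoxide, leaving an
# alkene (C3H2O) or, after water loss from the sulfenic acid, a thiol
# (C3H2OS) remnant on lysine; the alkene/thiol pair produces the
# characteristic 31.9721 Da doublet. The intact added mass is C6H6O3S.
#
# DSBSO carries two sulfoxide cleavage sites; its light remnant is the same
# alkene while the heavy remnant retains the dimethyl-dioxide/sulfoxide core
# (C8H12O4S2), giving a 182.0071 Da doublet. Intact added mass C11H16O6S2
# (308.0388 Da).
BUILTIN_CROSSLINKERS <- list(
  DSSO = list(
    short = c("C3H2O", "alkene"), long = c("C3H2OS", "thiol"),
    intact = "C6H6O3S"
  ),
  DSBSO = list(
    short = c("C3H2O", "alkene"), long = c("C8H12O4S2", "sulfoxide core"),
    intact = "C11H16O6S2"
  )
)

#' Built-in cross-linker definitions
#'
#' Returns the built-in definition of an MS-cleavable cross-linker. Both
#' built-ins react with lysine side chains and protein N-termini
#' (NHS-ester chemistry).
#'
#' @param name `"DSSO"` or `"DSBSO"` (case-insensitive).
#' @return A [crosslinker_spec()].
#' @examples
#' doublet_delta(crosslinker("DSSO"))   # 31.9721
#' doublet_delta(crosslinker("DSBSO"))  # 182.0071
#' @export
crosslinker <- function(name) {
  key <- toupper(name)
  if (!key %in% names(BUILTIN_CROSSLINKERS)) {
    stop("unknown cross-linker '", name, "'; built-ins: ",
         paste(names(BUILTIN_CROSSLINKERS), collapse = ", "))
  }
  b <- BUILTIN_CROSSLINKERS[[key]]
  crosslinker_spec(
    name = key,
    reactive_residues = "K",
    protein_nterm_reactive = TRUE,
    short_arm = arm_fragment("short", b$short[1]),
    long_arm = arm_fragment("long", b$long[1]),
    products = empty_products(),
    intact_mass = mass_from_composition(b$intact)
  )
}

#' Load a cross-linker specification from a YAML config or by name
#'
#' A config file carries fields `name`, `short_arm`, `long_arm` (each either
#' an elemental `composition` or a `mono_mass`), `reactive_residues`,
#' `nterm`, `intact_mass` (or `intact_composition`), and an optional
#' `products` list of `{label, delta_mass, applies_to}` entries. A bare
#' built-in name (`"DSSO"`, `"DSBSO"`) is resolved without file access.
#'
#' @param config Path to a YAML file, or a built-in cross-linker name.
#' @return A validated [crosslinker_spec()].
#' @export
load_crosslinker <- function(config) {
  if (toupper(config) %in% names(BUILTIN_CROSSLINKERS)) {
    return(crosslinker(config))
  }
  if (!file.exists(config)) {
    stop("unknown cross-linker '", config,
         "': not a built-in name and no such config file")
  }
  cfg <- yaml::read_yaml(config)
  parse_arm <- function(node, label) {
    arm_fragment(label,
                 composition = if (!is.null(node$composition)) node$composition else NA_character_,
                 mono_mass = node$mono_mass)
  }
  products <- empty_products()
  if (!is.null(cfg$products) && length(cfg$products)) {
    products <- do.call(rbind, lapply(cfg$products, function(p) {
      data.frame(label = p$label, delta_mass = as.numeric(p$delta_mass),
                 applies_to = if (is.null(p$applies_to)) "both" else p$applies_to,
                 stringsAsFactors = FALSE)
    }))
  }
  intact <- if (!is.null(cfg$intact_mass)) as.numeric(cfg$intact_mass)
            else mass_from_composition(cfg$intact_composition)
  crosslinker_spec(
    name = cfg$name,
    reactive_residues = unlist(strsplit(paste(cfg$reactive_residues, collapse = ""), "")),
    protein_nterm_reactive = isTRUE(cfg$nterm),
    short_arm = parse_arm(cfg$short_arm, "short"),
    long_arm = parse_arm(cfg$long_arm, "long"),
    products = products,
    intact_mass = intact
  )
}

#' Write a cross-linker specification to a YAML config
#'
#' Inverse of [load_crosslinker()]: `load_crosslinker(save_crosslinker(spec, f))`
#' reproduces `spec` field by field.
#'
#' @param spec A [crosslinker_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_crosslinker <- function(spec, path) {
  stopifnot(inherits(spec, "crosslinker_spec"))
  arm_node <- function(a) {
    n <- list(mono_mass = a$mono_mass)
    if (!is.na(a$composition)) n$composition <- a$composition
    n
  }
  cfg <- list(
    name = spec$name,
    reactive_residues = paste(spec$reactive_residues, collapse = ""),
    nterm = spec$protein_nterm_reactive,
    short_arm = arm_node(spec$short_arm),
    long_arm = arm_node(spec$long_arm),
    intact_mass = spec$intact_mass
  )
  if (nrow(spec$products)) {
    cfg$products <- lapply(seq_len(nrow(spec$products)), function(i) {
      as.list(spec$products[i, c("label", "delta_mass", "applies_to")])
    })
  }
  yaml::write_yaml(cfg, path, precision = 12L)
  invisible(path)
}

# Enumerated (product, delta) combinations searched per arm: no product plus
# each single product applicable to that arm. Multi-product stacking is not
# enumerated (combinatorial guard).
arm_product_deltas <- function(spec, arm) {
  out <- data.frame(label = NA_character_, delta_mass = 0.0,
                    stringsAsFactors = FALSE)
  p <- spec$products
  if (nrow(p)) {
    side <- if (arm == "light") "short" else "long"
    p <- p[p$applies_to %in% c(side, "both"), , drop = FALSE]
    if (nrow(p)) {
      out <- rbind(out, data.frame(label = p$label, delta_mass = p$delta_mass,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}
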