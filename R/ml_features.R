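# Salt descriptor construction for the uptake classifier. Features are
# physicochemical and biological descriptors of the constituent ions:
# charges, masses, periodic-table groups and nutrient categories. The
# bundled ion table covers every ion occurring in the package's 29-salt
# panel; the feature schema is a documented superset of "chemical groups,
# relative masses, ion charges and biological relevance".

NUTRIENT_CLASS_LEVELS <- c("macronutrient", "secondary_nutrient",
                           "micronutrient", "sodium", "heavy_metal",
                           "neutral")

#' Bundled ion property reference table
#'
#' Charges, molar masses (g/mol), periodic-table group of the central
#' element, and nutrient class for the cations and anions of the package's
#' salt panel.
#'
#' @return Data.frame with columns `ion`, `kind`, `charge`, `mass_g_mol`,
#'   `periodic_group`, `nutrient_class`.
#' @export
ion_reference_table <- function() {
  path <- system.file("extdata", "ion_properties.csv", package = "rhizosense",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' The package's salt panel
#'
#' The 29 inorganic salts the pipeline's calibration and uptake machinery is
#' exercised with.
#'
#' @return Character vector of salt formulas.
#' @export
salt_panel <- function() {
  c("AgNO3", "BaCl2", "CaCl2", "Ca(NO3)2", "CdCl2", "Cd(NO3)2", "CdSO4",
    "CuCl2", "Cu(NO3)2", "CuSO4", "GdCl3", "KCl", "KH2PO4", "KNO3", "K2SO4",
    "LaCl3", "MgCl2", "Mg(NO3)2", "NaCl", "NaH2PO4", "NaNO3", "Na2CO3",
    "Na2SO4", "NaOH", "NH4Cl", "NH4H2PO4", "NH4NO3", "Ni(NO3)2", "NiCl2")
}

# Parse a salt formula like "Ca(NO3)2", "K2SO4", "NH4H2PO4" into its cation,
# anion and stoichiometric counts, validated for charge neutrality.
parse_salt_formula <- function(salt_name, ions = ion_reference_table()) {
  cations <- ions[ions$kind == "cation", ]
  anions <- ions[ions$kind == "anion", ]
  cat_syms <- cations$ion[order(-nchar(cations$ion))]
  an_syms <- anions$ion[order(-nchar(anions$ion))]

  rest <- NULL; cat_sym <- NULL; n_cat <- 1L
  for (s in cat_syms) {
    if (startsWith(salt_name, s)) {
      tail_str <- substring(salt_name, nchar(s) + 1L)
      m <- regmatches(tail_str, regexec("^([0-9]*)(.*)$", tail_str))[[1L]]
      cand_n <- if (nzchar(m[2L])) as.integer(m[2L]) else 1L
      cat_sym <- s; n_cat <- cand_n; rest <- m[3L]
      break
    }
  }
  if (is.null(cat_sym)) {
    # identify a known anion tail so the error can name the unknown prefix
    for (s in an_syms) {
      mm <- regmatches(salt_name,
                       regexec(paste0("^(.*?)\\(?", s, "\\)?[0-9]*$"), salt_name))[[1L]]
      if (length(mm) == 2L && nzchar(mm[2L])) {
        stop(sprintf("unknown cation '%s' in salt '%s'", mm[2L], salt_name),
             call. = FALSE)
      }
    }
    stop(sprintf("cannot parse salt formula '%s'", salt_name), call. = FALSE)
  }
  an_sym <- NULL; n_an <- 1L
  if (startsWith(rest, "(")) {
    m <- regmatches(rest, regexec("^\\(([A-Za-z0-9]+)\\)([0-9]*)$", rest))[[1L]]
    if (length(m) != 3L || !(m[2L] %in% anions$ion)) {
      stop(sprintf("unknown anion '%s' in salt '%s'",
                   if (length(m) == 3L) m[2L] else rest, salt_name),
           call. = FALSE)
    }
    an_sym <- m[2L]
    n_an <- if (nzchar(m[3L])) as.integer(m[3L]) else 1L
  } else {
    for (s in an_syms) {
      m <- regmatches(rest, regexec(paste0("^", s, "([0-9]*)$"), rest))[[1L]]
      if (length(m) == 2L) {
        an_sym <- s
        n_an <- if (nzchar(m[2L])) as.integer(m[2L]) else 1L
        break
      }
    }
    if (is.null(an_sym)) {
      stop(sprintf("unknown anion '%s' in salt '%s'", rest, salt_name),
           call. = FALSE)
    }
  }
  qc <- cations$charge[cations$ion == cat_sym]
  qa <- anions$charge[anions$ion == an_sym]
  if (qc * n_cat + qa * n_an != 0) {
    stop(sprintf(
      "ambiguous formula '%s': charges do not balance (%d x %+d cation, %d x %+d anion)",
      salt_name, n_cat, qc, n_an, qa), call. = FALSE)
  }
  list(cation = cat_sym, anion = an_sym, n_cation = n_cat, n_anion = n_an)
}

#' Build the salt descriptor table
#'
#' Deterministically maps salt formulas to feature vectors of their
#' constituent ions using the bundled ion property table. Unknown ions are
#' an error naming the offending symbol.
#'
#' @param salt_names Character vector of salt formulas, e.g. `"KNO3"`.
#' @return Data.frame with one row per salt: symbols, signed charges,
#'   ion masses and total molar mass (g/mol), stoichiometric counts,
#'   periodic-table groups and nutrient classes of both ions.
#' @examples
#' build_feature_table(c("KNO3", "LaCl3"))
#' @export
build_feature_table <- function(salt_names) {
  ions <- ion_reference_table()
  rows <- lapply(salt_names, function(sn) {
    p <- parse_salt_formula(sn, ions)
    ci <- ions[ions$ion == p$cation & ions$kind == "cation", ]
    ai <- ions[ions$ion == p$anion & ions$kind == "anion", ]
    data.frame(
      salt_name = sn,
      cation_symbol = p$cation, anion_symbol = p$anion,
      n_cation = p$n_cation, n_anion = p$n_anion,
      cation_charge = ci$charge, anion_charge = ai$charge,
      cation_mass = ci$mass_g_mol, anion_mass = ai$mass_g_mol,
      salt_molar_mass = p$n_cation * ci$mass_g_mol + p$n_anion * ai$mass_g_mol,
      cation_group = ci$periodic_group, anion_group = ai$periodic_group,
      cation_nutrient_class = ci$nutrient_class,
      anion_nutrient_class = ai$nutrient_class,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Numeric feature matrix for the classifier
#'
#' Encodes a descriptor table as a numeric matrix: numeric columns pass
#' through, the two nutrient-class columns are one-hot encoded over the
#' fixed class vocabulary so the encoding does not depend on which classes
#' happen to occur in a particular dataset.
#'
#' @param features Data.frame from [build_feature_table()].
#' @return Numeric matrix, one row per salt.
#' @export
feature_matrix <- function(features) {
  num_cols <- c("n_cation", "n_anion", "cation_charge", "anion_charge",
                "cation_mass", "anion_mass", "salt_molar_mass",
                "cation_group", "anion_group")
  m <- as.matrix(features[, num_cols])
  onehot <- function(values, prefix) {
    out <- sapply(NUTRIENT_CLASS_LEVELS,
                  function(lv) as.numeric(values == lv))
    if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
    colnames(out) <- paste0(prefix, "_", NUTRIENT_CLASS_LEVELS)
    out
  }
  cbind(m, onehot(features$cation_nutrient_class, "cation_class"),
        onehot(features$anion_nutrient_class, "anion_class"))
}

#' Bin normalized uptake ratios into range classes
#'
#' The two-range model separates uptake (`ratio > 1`) from no uptake
#' (`ratio <= 1`). For 3-6 ranges the first boundary stays fixed at 1 and
#' the remaining bins split `(1, max(ratios)]` into equal widths, the top
#' bin right-closed. Labels are integers `0 .. n_ranges - 1` from lowest to
#' highest uptake.
#'
#' @param ratios Finite numeric vector of normalized uptake ratios.
#' @param n_ranges Number of classes, 2 to 6.
#' @return Integer vector of labels with a `boundaries` attribute (the
#'   internal bin edges, excluding the infinite outer edges).
#' @examples
#' bin_uptake(c(0.5, 3, 5, 7), 4)
#' @export
bin_uptake <- function(ratios, n_ranges) {
  n_ranges <- as.integer(n_ranges)
  if (is.na(n_ranges) || n_ranges < 2L || n_ranges > 6L) {
    stop("n_ranges must be between 2 and 6", call. = FALSE)
  }
  if (length(ratios) == 0L) stop("empty ratio vector", call. = FALSE)
  if (any(!is.finite(ratios))) stop("ratios must be finite", call. = FALSE)
  if (n_ranges == 2L) {
    labels <- as.integer(ratios > 1)
    attr(labels, "boundaries") <- 1
    return(labels)
  }
  top <- max(ratios)
  if (top <= 1) {
    labels <- rep(0L, length(ratios))
    attr(labels, "boundaries") <- 1
    return(labels)
  }
  width <- (top - 1) / (n_ranges - 1L)
  edges <- 1 + width * seq(0L, n_ranges - 1L)   # inner edges incl. top
  labels <- integer(length(ratios))
  above <- ratios > 1
  # bins (1, 1+w], (1+w, 1+2w], ..., top bin right-closed at max
  labels[above] <- pmin(n_ranges - 1L,
                        as.integer(ceiling((ratios[above] - 1) / width)))
  attr(labels, "boundaries") <- edges
  labels
}

#' F1 score from a confusion matrix
#'
#' Rows index the experimentally derived class, columns the predicted class.
#' Per-class precision and recall use the 0/0 -> 0 convention;
#' `averaging = "macro"` averages per-class F1 over classes that occur at
#' all (classes never present and never predicted are excluded),
#' `"micro"` pools counts, `"binary"` applies `2PR/(P+R)` to the positive
#' (last, highest-uptake) class of a 2x2 matrix.
#'
#' @param confusion Square non-negative integer matrix.
#' @param averaging `"macro"`, `"micro"` or `"binary"`.
#' @return F1 in \[0, 1\].
#' @examples
#' f1_from_confusion(matrix(c(5, 5, 5, 5), 2), "binary")
#' @export
f1_from_confusion <- function(confusion, averaging = c("macro", "micro", "binary")) {
  averaging <- match.arg(averaging)
  confusion <- as.matrix(confusion)
  if (length(confusion) == 0L || nrow(confusion) != ncol(confusion)) {
    stop("confusion must be a non-empty square matrix", call. = FALSE)
  }
  if (any(confusion < 0)) stop("confusion counts must be non-negative",
                               call. = FALSE)
  k <- nrow(confusion)
  tp <- diag(confusion)
  pred_tot <- colSums(confusion)
  act_tot <- rowSums(confusion)
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  if (averaging == "micro") {
    p <- safe_div(sum(tp), sum(pred_tot))
    r <- safe_div(sum(tp), sum(act_tot))
    return(if (p + r == 0) 0 else 2 * p * r / (p + r))
  }
  if (averaging == "binary") {
    if (k != 2L) stop("binary averaging needs a 2x2 confusion", call. = FALSE)
    p <- safe_div(tp[2L], pred_tot[2L])
    r <- safe_div(tp[2L], act_tot[2L])
    return(unname(if (p + r == 0) 0 else 2 * p * r / (p + r)))
  }
  present <- act_tot > 0 | pred_tot > 0
  if (!any(present)) stop("confusion matrix is all zero", call. = FALSE)
  p <- safe_div(tp, pred_tot)
  r <- safe_div(tp, act_tot)
  f1 <- ifelse(p + r == 0, 0, 2 * p * r / (p + r))
  mean(f1[present])
}
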