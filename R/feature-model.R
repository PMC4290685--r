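# Residue data model: coordinates from PDB, per-residue attribute tables,
# and min-max normalization of attributes to [0, 1].

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Names of the 26 per-residue attribute columns
#'
#' The node label of every residue is a 26-vector: relative solvent
#' accessibility (`rasa`), electrostatic potential (`ep`), sequence entropy
#' (`entropy`), surface curvature (`curv`), pocket size (`pocket`),
#' structural conservation (`strcn`), and the 20 PSSM log-odds columns
#' (`pssm_A` ... `pssm_V`, standard PSI-BLAST residue order
#' ARNDCQEGHILKMFPSTWYV).
#'
#' @return Character vector of length 26, in the fixed column order.
#' @export
attribute_names <- function() {
  c("rasa", "ep", "entropy", "curv", "pocket", "strcn", paste0("pssm_", AA20))
}

# Named attribute groups: the seven features of the method. "pssm" is one
# feature spanning 20 columns.
FEATURE_GROUPS <- list(
  rasa = "rasa", ep = "ep", entropy = "entropy", curv = "curv",
  pocket = "pocket", strcn = "strcn", pssm = paste0("pssm_", AA20)
)

#' Resolve feature names to attribute columns
#'
#' @param features Character vector of feature group names (any of
#'   `"rasa"`, `"ep"`, `"entropy"`, `"curv"`, `"pocket"`, `"strcn"`,
#'   `"pssm"`) or `"all"` (default).
#' @return Character vector of attribute column names.
#' @export
feature_columns <- function(features = "all") {
  if (identical(features, "all")) return(attribute_names())
  bad <- setdiff(features, names(FEATURE_GROUPS))
  if (length(bad) > 0) {
    stop("unknown feature(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unlist(FEATURE_GROUPS[features], use.names = FALSE)
}

#' Van der Waals radii used by the contact rule
#'
#' Heavy-atom radii in Angstroms, by element symbol. Unlisted elements fall
#' back to the carbon radius.
#'
#' @param override Named numeric vector of per-element overrides, e.g.
#'   `c(C = 1.75)`.
#' @return Named numeric vector of radii.
#' @export
default_radii <- function(override = NULL) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  if (!is.null(override)) {
    stopifnot(is.numeric(override), !is.null(names(override)))
    r[names(override)] <- override
  }
  r
}

element_radius <- function(element, radii = default_radii()) {
  out <- unname(radii[element])
  out[is.na(out)] <- radii[["C"]]
  out
}

#' Build the canonical residue key
#'
#' Residues are identified by `(chain, resnum, icode)`; keys are the
#' colon-joined string `"chain:resnum:icode"` (empty insertion code allowed).
#'
#' @param chain Chain identifier(s).
#' @param resnum Residue number(s), 1-based as in PDB.
#' @param icode Insertion code(s); `""` or `NA` for none.
#' @return Character vector of keys.
#' @export
residue_key <- function(chain, resnum, icode = "") {
  icode <- ifelse(is.na(icode), "", icode)
  paste(chain, resnum, icode, sep = ":")
}

# Add the key column to any residue-shaped tibble.
with_keys <- function(df) {
  dplyr::mutate(df, key = residue_key(.data$chain, .data$resnum, .data$icode))
}

#' Read heavy-atom protein coordinates from a PDB file
#'
#' Parses a standard PDB file and returns one row per residue with an
#' `atoms` list-column. Hydrogens, waters and all HETATM records are
#' excluded; alternate locations are resolved to the highest-occupancy
#' conformer (first-listed on ties).
#'
#' @param pdb_path Path to a PDB file.
#' @param protein_id Identifier stored in the `protein_id` column; defaults
#'   to the file name without extension.
#' @param radii Radius table from [default_radii()].
#' @return A tibble with columns `protein_id`, `chain`, `resnum`, `icode`,
#'   `aa` (1-letter code), `key`, and `atoms` (list of tibbles with `name`,
#'   `element`, `x`, `y`, `z`, `radius`).
#' @export
read_structure <- function(pdb_path, protein_id = NULL,
                           radii = default_radii()) {
  if (!file.exists(pdb_path)) {
    stop("PDB file not found: ", pdb_path, call. = FALSE)
  }
  if (is.null(protein_id)) {
    protein_id <- sub("\\.[^.]*$", "", basename(pdb_path))
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(pdb_path, verbose = FALSE,
                                     rm.alt = FALSE)),
    error = function(e) {
      stop("could not parse PDB file '", pdb_path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  at <- tibble::as_tibble(pdb$atom)
  at <- dplyr::filter(
    at,
    .data$type == "ATOM",
    !.data$resid %in% c("HOH", "WAT", "DOD"),
    is.na(.data$elesy) | .data$elesy != "H"
  )
  # Some files lack the element column; fall back on the atom-name prefix.
  at <- dplyr::filter(at, !grepl("^[0-9]*H", .data$elety))
  if (nrow(at) == 0) {
    stop("no protein heavy atoms found in '", pdb_path, "'", call. = FALSE)
  }
  at <- dplyr::mutate(
    at,
    insert = ifelse(is.na(.data$insert), "", .data$insert),
    alt = ifelse(is.na(.data$alt), "", .data$alt),
    o = ifelse(is.na(.data$o), 1, .data$o),
    elesy = ifelse(is.na(.data$elesy) | .data$elesy == "",
                   substr(trimws(.data$elety), 1, 1), .data$elesy),
    .row = dplyr::row_number()
  )
  # altloc: keep the highest-occupancy record per (residue, atom name);
  # ties go to the first-listed record.
  at <- at |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$.row, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row)

  res <- at |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$resid) |>
    dplyr::summarise(
      atoms = list(tibble::tibble(
        name = trimws(elety),
        element = elesy,
        x = x, y = y, z = z,
        radius = element_radius(elesy, radii)
      )),
      .order = min(.data$.row),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$.order)

  out <- tibble::tibble(
    protein_id = protein_id,
    chain = res$chain,
    resnum = as.integer(res$resno),
    icode = res$insert,
    aa = unname(bio3d::aa321(res$resid)),
    atoms = res$atoms
  )
  out <- with_keys(out)
  if (anyDuplicated(out$key) > 0) {
    stop("duplicate residue keys in '", pdb_path, "'", call. = FALSE)
  }
  out
}

feature_table_columns <- function(with_strcn = TRUE) {
  base <- c("protein_id", "chain", "resnum", "icode", "aa",
            "asa_complex", "asa_unbound", "rel_acc")
  attrs <- attribute_names()
  if (!with_strcn) attrs <- setdiff(attrs, "strcn")
  c(base, attrs)
}

#' Read a per-residue feature table
#'
#' Reads the tab-separated attribute table carrying, for every residue, the
#' 26 node attributes plus solvent-accessible surface areas in the bound
#' complex and the unbound protein and the relative accessibility. The
#' header must be exactly
#' `protein_id chain resnum icode aa asa_complex asa_unbound rel_acc rasa ep
#' entropy curv pocket strcn pssm_A ... pssm_V`. A table lacking the
#' `strcn` column is accepted in PSSM-only mode (structural conservation
#' unavailable, as for proteins without structural neighbors): `strcn` is
#' filled with `NA` and the returned tibble carries attribute
#' `pssm_only = TRUE`.
#'
#' @param tsv_path Path to the TSV file.
#' @return Tibble with one row per residue, a `key` column, and attribute
#'   `pssm_only` (logical).
#' @export
read_feature_table <- function(tsv_path) {
  if (!file.exists(tsv_path)) {
    stop("feature table not found: ", tsv_path, call. = FALSE)
  }
  hdr <- strsplit(readLines(tsv_path, n = 1L), "\t", fixed = TRUE)[[1]]
  pssm_only <- FALSE
  if (identical(hdr, feature_table_columns(with_strcn = FALSE))) {
    pssm_only <- TRUE
  } else if (!identical(hdr, feature_table_columns())) {
    stop("feature table header does not match the column contract (",
         length(hdr), " columns found, ", length(feature_table_columns()),
         " expected): ", tsv_path, call. = FALSE)
  }
  num_cols <- setdiff(hdr, c("protein_id", "chain", "aa", "icode"))
  spec <- readr::cols(.default = readr::col_character())
  tab <- readr::read_tsv(tsv_path, col_types = spec, progress = FALSE,
                         na = character())
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    bad <- which(is.na(v) & tab[[cc]] != "NA")
    if (length(bad) > 0) {
      stop("non-numeric value in column '", cc, "', row ", bad[1],
           " of ", tsv_path, call. = FALSE)
    }
    tab[[cc]] <- v
  }
  tab$resnum <- as.integer(tab$resnum)
  if (pssm_only) tab$strcn <- NA_real_
  tab <- tab[, feature_table_columns()]
  tab <- with_keys(tibble::as_tibble(tab))
  if (any(stats::na.omit(c(tab$asa_complex, tab$asa_unbound)) < 0)) {
    stop("negative ASA value in ", tsv_path, call. = FALSE)
  }
  attr(tab, "pssm_only") <- pssm_only
  tab
}

#' Write a per-residue feature table
#'
#' Inverse of [read_feature_table()]; writes the fixed-header TSV dialect.
#'
#' @param features Tibble as returned by [read_feature_table()] (or the
#'   feature columns of a generated protein).
#' @param tsv_path Output path.
#' @param pssm_only Drop the `strcn` column (PSSM-only mode). Defaults to
#'   the table's own `pssm_only` attribute.
#' @return `tsv_path`, invisibly.
#' @export
write_feature_table <- function(features, tsv_path, pssm_only = NULL) {
  if (is.null(pssm_only)) {
    pssm_only <- isTRUE(attr(features, "pssm_only"))
  }
  cols <- feature_table_columns(with_strcn = !pssm_only)
  out <- features[, cols]
  readr::write_tsv(out, tsv_path, progress = FALSE)
  invisible(tsv_path)
}

#' Join structure and features into one residue table
#'
#' Matches rows by residue key within one protein and carries both the
#' `atoms` list-column and the 26 attribute columns. Every structure residue
#' must have a feature row.
#'
#' @param structure Tibble from [read_structure()].
#' @param features Tibble from [read_feature_table()].
#' @return Combined residue tibble.
#' @export
attach_features <- function(structure, features) {
  feat <- dplyr::select(features, -dplyr::any_of(c("protein_id", "aa")))
  out <- dplyr::inner_join(structure, feat,
                           by = c("chain", "resnum", "icode", "key"))
  missing <- setdiff(structure$key, out$key)
  if (length(missing) > 0) {
    stop("no feature row for residue(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  attr(out, "pssm_only") <- isTRUE(attr(features, "pssm_only"))
  out
}

#' Fit a min-max attribute normalizer
#'
#' Records, for each attribute column, the minimum and maximum over all
#' residues of the (training) table. The kernel compares residues across
#' proteins, so scaling is dataset-wide over the union of training residues
#' rather than per protein.
#'
#' @param residues Residue tibble (one or many proteins) carrying the
#'   attribute columns.
#' @param columns Attribute columns to normalize; defaults to all 26.
#' @return An object of class `patch_normalizer`.
#' @export
fit_normalizer <- function(residues, columns = attribute_names()) {
  if (nrow(residues) < 1) stop("cannot fit normalizer on 0 residues",
                               call. = FALSE)
  rng <- purrr::map_dfr(columns, function(cc) {
    v <- residues[[cc]]
    tibble::tibble(
      attribute = cc,
      min = if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE),
      max = if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    )
  })
  structure(list(ranges = rng), class = "patch_normalizer")
}

#' Apply a fitted normalizer
#'
#' Min-max scales each attribute using the training-set extremes and clips
#' results into \[0, 1\]. A constant attribute maps to 0.
#'
#' @param residues Residue tibble.
#' @param normalizer A `patch_normalizer` from [fit_normalizer()].
#' @return The residue tibble with scaled attribute columns and attribute
#'   `normalized = TRUE`.
#' @export
apply_normalizer <- function(residues, normalizer) {
  if (!inherits(normalizer, "patch_normalizer")) {
    stop("not a fitted patch_normalizer", call. = FALSE)
  }
  if (is_normalized(residues)) return(residues)  # idempotent
  rng <- normalizer$ranges
  for (i in seq_len(nrow(rng))) {
    cc <- rng$attribute[i]
    lo <- rng$min[i]; hi <- rng$max[i]
    v <- residues[[cc]]
    if (is.na(lo) || is.na(hi) || hi <= lo) {
      scaled <- ifelse(is.na(v), NA_real_, 0)
    } else {
      scaled <- pmin(1, pmax(0, (v - lo) / (hi - lo)))
    }
    residues[[cc]] <- scaled
  }
  attr(residues, "normalized") <- TRUE
  residues
}

#' @export
print.patch_normalizer <- function(x, ...) {
  cat("<patch_normalizer> fitted on", nrow(x$ranges), "attributes\n")
  print(x$ranges, n = 6)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.patch_normalizer <- function(x, ...) x$ranges

is_normalized <- function(residues) {
  isTRUE(attr(residues, "normalized"))
}

#' Read a run configuration file
#'
#' YAML (or `key: value`) configuration with optional keys
#' `kernel.gamma`, `kernel.c`, and `radii` (a named map of per-element
#' radius overrides in Angstroms).
#'
#' @param path Path to a YAML file.
#' @return List with elements `params` (a [kernel_params()] object) and
#'   `radii` (a radius table).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  gamma <- cfg$kernel$gamma %||% 72
  cc <- cfg$kernel$c %||% 2
  override <- if (!is.null(cfg$radii)) unlist(cfg$radii) else NULL
  list(params = kernel_params(gamma = gamma, c = cc),
       radii = default_radii(override))
}
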