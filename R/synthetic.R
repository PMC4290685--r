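# Synthetic protein generator.
#
# Emits proteins with fully controlled ground truth so every stage of the
# pipeline is testable without external structures or feature tools:
# residues on a self-avoiding 3D random walk (one carbon-like atom each, so
# consecutive residues always satisfy the contact rule), a spatially
# contiguous interface cluster, and 26 attributes drawn from Gaussians
# whose means differ between interface and non-interface residues by a
# controllable separation on a random subset of attributes. ASA and
# relative-accessibility fields are synthesized so that the interface
# cluster passes the >= 1 A^2 ASA-loss rule and most residues pass the > 5%
# surface rule.

#' Generator configuration
#'
#' @param n_residues Residues per protein (>= 12; default 60).
#' @param n_proteins Proteins in a dataset (default 20).
#' @param separation Mean attribute shift (normalized units) between
#'   interface and non-interface residues on the shifted attributes
#'   (default 1.0; 0 makes the classes indistinguishable in expectation).
#' @param interface_fraction Fraction of residues in the interface cluster
#'   (default 0.2).
#' @param contact_spacing Distance between consecutive walk steps in
#'   Angstroms (default 3.8, within the carbon-carbon contact range).
#' @param noise_sd Gaussian attribute noise (default 0.15).
#' @param seed Root seed; all randomness derives from it.
#' @param n_shifted Number of attributes (of 26) carrying the class shift,
#'   drawn once per dataset (default 8, emulating a mix of informative and
#'   uninformative features).
#' @param buried_fraction Fraction of non-interface residues given
#'   relative accessibility below the surface cutoff (default 0.08, keeping
#'   >= 90% of residues on the surface).
#' @param atoms_per_residue 1 (default) for a single carbon atom, or up to
#'   5 to add small satellite atoms around each center (stress tests for
#'   the atom-pair contact rule).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_residues = 60, n_proteins = 20,
                             separation = 1.0, interface_fraction = 0.2,
                             contact_spacing = 3.8, noise_sd = 0.15,
                             seed = 1, n_shifted = 8,
                             buried_fraction = 0.08,
                             atoms_per_residue = 1) {
  stopifnot(n_residues >= 12, n_proteins >= 1, separation >= 0,
            interface_fraction > 0, interface_fraction < 1, noise_sd > 0,
            contact_spacing > 0, n_shifted >= 1, n_shifted <= 26,
            buried_fraction >= 0, buried_fraction < 0.1,
            atoms_per_residue >= 1, atoms_per_residue <= 5)
  structure(
    list(n_residues = n_residues, n_proteins = n_proteins,
         separation = separation, interface_fraction = interface_fraction,
         contact_spacing = contact_spacing, noise_sd = noise_sd,
         seed = as.integer(seed), n_shifted = n_shifted,
         buried_fraction = buried_fraction,
         atoms_per_residue = atoms_per_residue),
    class = "generator_config"
  )
}

# Self-avoiding random walk: unit-sphere steps of length `spacing`,
# rejecting points within `min_sep` of any earlier residue. The walk is
# confined to a sphere of radius ~ spacing * n^(1/3) around the origin so
# the chain packs into a globule: without confinement the chain stretches
# out and carries too few non-backbone contacts to resemble a folded
# protein surface.
random_walk <- function(n, spacing, min_sep = 3.0, max_tries = 200) {
  r_max <- spacing * n^(1 / 3)
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- 0
  for (i in 2:n) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      u <- rnorm(3)
      step <- u / sqrt(sum(u^2)) * spacing
      cand <- pos[i - 1, ] + step
      if (sum(cand^2) > r_max^2) next
      d2 <- rowSums((pos[seq_len(i - 1), , drop = FALSE] -
                       matrix(cand, i - 1, 3, byrow = TRUE))^2)
      if (all(d2 >= min_sep^2)) {
        pos[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  pos
}

# Size of the largest connected component of the point contact graph
# (edge iff distance < cutoff); breadth-first search.
largest_component <- function(points, cutoff) {
  m <- nrow(points)
  if (m == 0) return(0)
  d2 <- as.matrix(stats::dist(points))^2
  adj <- d2 < cutoff^2
  diag(adj) <- FALSE
  unvisited <- rep(TRUE, m)
  best <- 0
  while (any(unvisited)) {
    frontier <- which(unvisited)[1]
    comp <- frontier
    unvisited[frontier] <- FALSE
    while (length(frontier) > 0) {
      nxt <- which(unvisited & colSums(adj[frontier, , drop = FALSE]) > 0)
      unvisited[nxt] <- FALSE
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    best <- max(best, length(comp))
  }
  best
}

make_atoms <- function(center, n_atoms, radii) {
  if (n_atoms == 1) {
    return(tibble::tibble(name = "CA", element = "C",
                          x = center[1], y = center[2], z = center[3],
                          radius = element_radius("C", radii)))
  }
  elems <- c("C", rep(c("C", "N", "O", "S"), length.out = n_atoms - 1))
  offs <- rbind(0, matrix(rnorm(3 * (n_atoms - 1), sd = 0.8),
                          n_atoms - 1, 3))
  tibble::tibble(
    name = c("CA", paste0("X", seq_len(n_atoms - 1))),
    element = elems,
    x = center[1] + offs[, 1],
    y = center[2] + offs[, 2],
    z = center[3] + offs[, 3],
    radius = element_radius(elems, radii)
  )
}

#' Generate one synthetic protein
#'
#' @param config A [generator_config()].
#' @param protein_id Identifier (default `"synth1"`).
#' @param shifted_attrs Attribute names carrying the class shift; drawn
#'   from the protein's own seed when `NULL` (datasets draw them once and
#'   pass them in so the shift is shared across proteins).
#' @param radii Radius table.
#' @return Residue tibble (structure + features + ASA ground truth) with
#'   attributes `interface_keys` and `shifted_attrs`.
#' @export
generate_protein <- function(config, protein_id = "synth1",
                             shifted_attrs = NULL,
                             radii = default_radii()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_residues
  withr::with_seed(config$seed, {
    if (is.null(shifted_attrs)) {
      shifted_attrs <- sample(attribute_names(), config$n_shifted)
    }
    n_int <- ceiling(config$interface_fraction * n)
    n_buried <- floor(config$buried_fraction * n)
    cutoff <- 2 * element_radius("C", radii) + 0.5
    ok <- FALSE
    for (r in seq_len(25)) {
      pos <- random_walk(n, config$contact_spacing)
      if (is.null(pos)) next
      seed_res <- sample.int(n, 1)
      d2seed <- rowSums((pos - matrix(pos[seed_res, ], n, 3,
                                      byrow = TRUE))^2)
      int_idx <- order(d2seed)[seq_len(n_int)]  # spatially coherent cluster
      is_int <- seq_len(n) %in% int_idx
      buried <- if (n_buried > 0) sample(which(!is_int), n_buried)
                else integer(0)
      # the negative patch sampler needs a connected set of n_int
      # non-interface surface residues: redraw the structure if the
      # eligible contact graph has no component that large
      if (largest_component(pos[!is_int & !(seq_len(n) %in% buried), ,
                                drop = FALSE], cutoff) >= n_int) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("no feasible structure after bounded walk retries",
           call. = FALSE)
    }
    base <- matrix(rnorm(n * 26, mean = 0.4, sd = config$noise_sd), n, 26)
    colnames(base) <- attribute_names()
    shift_cols <- match(shifted_attrs, attribute_names())
    base[is_int, shift_cols] <- base[is_int, shift_cols] + config$separation
    base <- pmin(pmax(base, 0), 1)  # pmin/pmax keep dim from first arg

    asa_unbound <- runif(n, 30, 120)
    asa_complex <- ifelse(is_int,
                          asa_unbound - runif(n, 5, 30),
                          asa_unbound - runif(n, 0, 0.9))
    asa_complex <- pmax(0, asa_complex)
    rel_acc <- runif(n, 10, 60)
    if (n_buried > 0) rel_acc[buried] <- runif(n_buried, 0, 4.9)

    aa <- sample(AA20, n, replace = TRUE)
    atoms <- lapply(seq_len(n), function(i) {
      make_atoms(pos[i, ], config$atoms_per_residue, radii)
    })

    out <- tibble::tibble(
      protein_id = protein_id,
      chain = "A",
      resnum = seq_len(n),
      icode = "",
      aa = aa,
      atoms = atoms,
      asa_complex = asa_complex,
      asa_unbound = asa_unbound,
      rel_acc = rel_acc
    )
    out <- dplyr::bind_cols(out, tibble::as_tibble(base))
    out <- with_keys(out)
    attr(out, "interface_keys") <- out$key[is_int]
    attr(out, "shifted_attrs") <- shifted_attrs
    out
  })
}

#' Generate a synthetic dataset
#'
#' Independent proteins with per-protein derived seeds (`seed + index`);
#' the shifted attribute subset is drawn once from the root seed and shared
#' by all proteins. Optionally writes one PDB file and one feature-table
#' TSV per protein.
#'
#' @param config A [generator_config()].
#' @param out_dir If non-`NULL`, directory receiving `<id>.pdb` and
#'   `<id>.tsv` per protein (created if needed).
#' @return Combined residue tibble for all proteins, with attribute
#'   `shifted_attrs`.
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  shifted <- withr::with_seed(config$seed,
                              sample(attribute_names(), config$n_shifted))
  width <- max(2, nchar(as.character(config$n_proteins)))
  proteins <- purrr::map(seq_len(config$n_proteins), function(i) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    id <- sprintf("synth%0*d", width, i)
    generate_protein(cfg_i, protein_id = id, shifted_attrs = shifted)
  })
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (p in proteins) {
      id <- p$protein_id[1]
      write_protein_pdb(p, file.path(out_dir, paste0(id, ".pdb")))
      write_feature_table(p, file.path(out_dir, paste0(id, ".tsv")))
    }
  }
  out <- dplyr::bind_rows(proteins)
  attr(out, "shifted_attrs") <- shifted
  out
}

aa123 <- function(a) {
  unname(bio3d::aa123(a))
}

#' Write a residue table as a PDB file
#'
#' Standard fixed-width ATOM records (one per heavy atom) terminated by
#' END; round-trips through [read_structure()].
#'
#' @param residues Residue tibble with an `atoms` list-column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_pdb <- function(residues, path) {
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(residues))) {
    at <- residues$atoms[[i]]
    res3 <- aa123(residues$aa[i])
    for (j in seq_len(nrow(at))) {
      serial <- serial + 1L
      name4 <- if (nchar(at$name[j]) < 4) sprintf(" %-3s", at$name[j])
               else at$name[j]
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, name4, res3, residues$chain[i], residues$resnum[i],
        ifelse(residues$icode[i] == "", " ", residues$icode[i]),
        at$x[j], at$y[j], at$z[j], 1.0, 0.0, at$element[j]))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a dataset directory
#'
#' Loads every `<id>.pdb` / `<id>.tsv` pair written by [generate_dataset()]
#' (or prepared by hand in the same layout) and joins structure with
#' features.
#'
#' @param dir Directory containing paired files.
#' @param radii Radius table.
#' @return Combined residue tibble.
#' @export
read_dataset_dir <- function(dir, radii = default_radii()) {
  pdbs <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
  if (length(pdbs) == 0) stop("no .pdb files in ", dir, call. = FALSE)
  purrr::map_dfr(pdbs, function(pp) {
    id <- sub("\\.pdb$", "", basename(pp))
    tsv <- file.path(dir, paste0(id, ".tsv"))
    if (!file.exists(tsv)) stop("no feature table for ", id, call. = FALSE)
    attach_features(read_structure(pp, protein_id = id, radii = radii),
                    read_feature_table(tsv))
  })
}
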