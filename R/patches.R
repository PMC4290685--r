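# Interface/surface residue definitions and the three patch kinds:
# the interface patch (all interface residues), the size-matched contiguous
# non-interface patch, and centered surface patches (a residue plus its k
# nearest surface neighbors).

#' Interface residues of a protein
#'
#' A residue is an interface residue when its solvent-accessible surface
#' area in the protein-DNA complex is smaller than in the unbound protein by
#' at least 1 A^2 (inclusive threshold).
#'
#' @param residues Residue tibble with `asa_complex` and `asa_unbound`.
#' @param delta Minimum ASA loss in A^2 (default 1.0).
#' @return Character vector of residue keys.
#' @export
interface_residues <- function(residues, delta = 1.0) {
  miss <- is.na(residues$asa_complex) | is.na(residues$asa_unbound)
  if (any(miss)) {
    stop("missing ASA for residue(s): ",
         paste(head(residues$key[miss], 5), collapse = ", "), call. = FALSE)
  }
  residues$key[residues$asa_unbound - residues$asa_complex >= delta]
}

#' Surface residues of a protein
#'
#' A residue is a surface residue when its relative accessibility in the
#' unbound protein exceeds 5% (strict).
#'
#' @param residues Residue tibble with `rel_acc` (percent).
#' @param cutoff Relative accessibility cutoff in percent (default 5).
#' @return Character vector of residue keys.
#' @export
surface_residues <- function(residues, cutoff = 5.0) {
  miss <- is.na(residues$rel_acc)
  if (any(miss)) {
    stop("missing rel_acc for residue(s): ",
         paste(head(residues$key[miss], 5), collapse = ", "), call. = FALSE)
  }
  residues$key[residues$rel_acc > cutoff]
}

new_patch <- function(protein_id, keys, label, center = NA_character_) {
  tibble::tibble(
    protein_id = protein_id,
    center = center,
    label = label,
    size = length(keys),
    keys = list(keys)
  )
}

#' Extract the interface patch
#'
#' The interface patch of a protein is the set of all its interface
#' residues, treated as one labeled graph. No connectivity is imposed.
#'
#' @inheritParams interface_residues
#' @return One-row patch tibble (`protein_id`, `center`, `label`, `size`,
#'   `keys` list-column).
#' @export
extract_interface_patch <- function(residues, delta = 1.0) {
  keys <- interface_residues(residues, delta)
  if (length(keys) == 0) {
    stop("protein ", residues$protein_id[1], " has no interface residues",
         call. = FALSE)
  }
  new_patch(residues$protein_id[1], keys, "interface")
}

# Order keys by (chain, resnum, icode); the deterministic tie-break order.
order_keys <- function(residues, keys) {
  idx <- match(keys, residues$key)
  ord <- order(residues$chain[idx], residues$resnum[idx],
               residues$icode[idx])
  keys[ord]
}

#' Sample a contiguous non-interface surface patch
#'
#' Draws a size-matched negative example: a connected set of surface
#' residues, none of which is an interface residue. Growth starts at a
#' uniformly random eligible seed residue and repeatedly adds the closest
#' eligible surface residue in contact with the current patch; if growth
#' stalls the sampler restarts from a new seed (bounded restarts).
#'
#' @param residues Residue tibble for one protein.
#' @param size Number of residues (typically the interface patch size).
#' @param seed Integer seed; identical seeds give identical patches.
#' @param pad Contact rule padding in Angstroms (default 0.5).
#' @param max_restarts Bound on restarts before failing.
#' @return One-row patch tibble with label `non_interface`.
#' @export
sample_noninterface_patch <- function(residues, size, seed, pad = 0.5,
                                      max_restarts = 100) {
  surf <- surface_residues(residues)
  eligible <- setdiff(surf, interface_residues(residues))
  if (length(eligible) < size) {
    stop("only ", length(eligible), " non-interface surface residues; ",
         "cannot build a patch of size ", size, call. = FALSE)
  }
  sub <- residues[match(eligible, residues$key), ]
  D <- adjusted_distance_matrix(sub)
  contact <- D < pad
  diag(contact) <- FALSE
  n <- length(eligible)
  withr::with_seed(seed, {
    for (attempt in seq_len(max_restarts)) {
      current <- sample.int(n, 1)
      while (length(current) < size) {
        # closest eligible surface residue in contact with the patch
        cand <- setdiff(which(colSums(contact[current, , drop = FALSE]) > 0),
                        current)
        if (length(cand) == 0) break
        d_to_patch <- apply(D[current, cand, drop = FALSE], 2, min)
        current <- c(current, cand[which.min(d_to_patch)])
      }
      if (length(current) == size) {
        keys <- order_keys(residues, eligible[current])
        return(new_patch(residues$protein_id[1], keys, "non_interface"))
      }
    }
  })
  stop("could not sample a connected non-interface patch of size ", size,
       " after ", max_restarts, " restarts", call. = FALSE)
}

#' Centered surface patches
#'
#' For each surface residue, the patch containing the residue and its `k`
#' nearest surface neighbors (minimum heavy-atom distance metric, the same
#' metric as the contact rule; ties broken by residue key order). These are
#' the prediction-time patches: one patch, hence one vote score, per surface
#' residue.
#'
#' @param residues Residue tibble for one protein.
#' @param k Number of neighbors (default 5, giving patches of 6 residues).
#' @return Patch tibble with one row per surface residue, label `unknown`,
#'   `center` set to the defining residue key.
#' @export
centered_surface_patches <- function(residues, k = 5) {
  surf <- surface_residues(residues)
  if (length(surf) < k + 1) {
    stop("protein has ", length(surf), " surface residues; need > ", k,
         call. = FALSE)
  }
  sub <- residues[match(surf, residues$key), ]
  sub <- sub[order(sub$chain, sub$resnum, sub$icode), ]
  surf <- sub$key
  D <- adjusted_distance_matrix(sub)
  purrr::map_dfr(seq_along(surf), function(i) {
    if (k == 0) {
      keys <- surf[i]
    } else {
      d <- D[i, ]
      d[i] <- Inf
      nn <- order(d)[seq_len(k)]  # rows are in key order, so ties break by key
      keys <- order_keys(sub, c(surf[i], surf[nn]))
    }
    new_patch(sub$protein_id[1], keys, "unknown", center = surf[i])
  })
}

#' Write a patch list to TSV
#'
#' @param patches Patch tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patch_table <- function(patches, path) {
  out <- tibble::tibble(
    protein_id = patches$protein_id,
    center = ifelse(is.na(patches$center), "", patches$center),
    residues = purrr::map_chr(patches$keys, paste, collapse = ","),
    label = patches$label
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
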