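#' Bead roles
#'
#' The semantic roles a (residue, bead) pair can take in the analyses:
#' lipid phosphate head bead, lipid tail bead, other lipid bead, cation
#' hydrophilic head (imidazolium ring), cation alkyl tail bead, anion, and
#' water.
#'
#' @export
bead_roles <- c("phosphate", "lipid_tail", "lipid_other",
                "cation_head", "cation_tail", "anion", "water")

#' Role map: (residue, bead) -> semantic role
#'
#' @param rules A data.frame with character columns `residue_name`,
#'   `bead_name`, `role`. Each (residue, bead) pair may map to at most one
#'   role, and every role must be one of [bead_roles].
#' @return An object of class `role_map`.
#' @seealso [read_role_map()], [default_role_map()]
#' @export
role_map <- function(rules) {
  need <- c("residue_name", "bead_name", "role")
  if (!is.data.frame(rules) || !all(need %in% names(rules))) {
    stop("role_map: rules must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  rules <- rules[, need]
  bad <- setdiff(unique(rules$role), bead_roles)
  if (length(bad)) {
    stop("role_map: unknown role(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(rules$residue_name, rules$bead_name)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    stop("role_map: duplicate (residue, bead) rule(s): ",
         paste(unique(dup), collapse = "; "), call. = FALSE)
  }
  structure(list(rules = rules), class = "role_map")
}

#' @export
print.role_map <- function(x, ...) {
  cat("<role_map>", nrow(x$rules), "rules over roles:",
      paste(sort(unique(x$rules$role)), collapse = ", "), "\n")
  invisible(x)
}

#' Role map for the synthetic bead naming convention
#'
#' Covers the beads emitted by the synthetic-system generators: DPPC-like
#' lipids (`PO4` phosphate, `C1A`..`C4A` / `C1B`..`C4B` tails, `GL` glycerol
#' linker), imidazolium-like cations (`RNG` ring, `CT1`.. tail beads), a
#' single-bead anion (`ANI`) and water (`W`).
#'
#' @param n_cation_tail Maximum number of cation tail beads to map.
#' @return A `role_map`.
#' @export
default_role_map <- function(n_cation_tail = 16) {
  rules <- rbind(
    data.frame(residue_name = "DPPC", bead_name = "PO4", role = "phosphate"),
    data.frame(residue_name = "DPPC", bead_name = "GL", role = "lipid_other"),
    data.frame(residue_name = "DPPC",
               bead_name = c(paste0("C", 1:4, "A"), paste0("C", 1:4, "B")),
               role = "lipid_tail"),
    data.frame(residue_name = "IMI", bead_name = "RNG", role = "cation_head"),
    data.frame(residue_name = "IMI", bead_name = paste0("CT", seq_len(n_cation_tail)),
               role = "cation_tail"),
    data.frame(residue_name = "BF4", bead_name = "ANI", role = "anion"),
    data.frame(residue_name = "W", bead_name = "W", role = "water"))
  role_map(rules)
}

#' Read / write a role map as a YAML config
#'
#' The config has one section per role, each a list of `{residue, bead}`
#' pairs:
#' ```yaml
#' phosphate:
#'   - {residue: DPPC, bead: PO4}
#' lipid_tail:
#'   - {residue: DPPC, bead: C1A}
#' ```
#'
#' @param path Path to the YAML file.
#' @return `read_role_map()` a `role_map`; `write_role_map()` `path`,
#'   invisibly.
#' @export
read_role_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), bead_roles)
  if (length(bad)) {
    stop("read_role_map: unknown role section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  for (role in names(cfg)) {
    for (pair in cfg[[role]]) {
      if (is.null(pair$residue) || is.null(pair$bead)) {
        stop("read_role_map: entries need 'residue' and 'bead' keys (role ",
             role, ")", call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        residue_name = as.character(pair$residue),
        bead_name = as.character(pair$bead), role = role)
    }
  }
  role_map(do.call(rbind, rows))
}

#' @rdname read_role_map
#' @param map A `role_map`.
#' @export
write_role_map <- function(map, path) {
  stopifnot(inherits(map, "role_map"))
  out <- lapply(split(map$rules, map$rules$role), function(d) {
    lapply(seq_len(nrow(d)), function(i) {
      list(residue = d$residue_name[i], bead = d$bead_name[i])
    })
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Bead indices matching a role (ungrouped)
#'
#' @param frame A `cg_frame`.
#' @param map A `role_map`.
#' @param role One of [bead_roles].
#' @return Integer vector of indices into `frame$atoms`.
#' @export
role_indices <- function(frame, map, role) {
  stopifnot(inherits(map, "role_map"))
  if (!role %in% bead_roles) {
    stop("unknown role '", role, "'; expected one of: ",
         paste(bead_roles, collapse = ", "), call. = FALSE)
  }
  r <- map$rules[map$rules$role == role, , drop = FALSE]
  key <- paste(frame$atoms$residue_name, frame$atoms$bead_name)
  which(key %in% paste(r$residue_name, r$bead_name))
}

#' Select beads by role, grouped by molecule
#'
#' Returns the beads of `frame` whose (residue, bead) pair maps to `role`,
#' grouped by `molecule_id`. An empty selection is not an error; a message
#' notes it.
#'
#' @param frame A `cg_frame`.
#' @param map A `role_map`.
#' @param role One of [bead_roles].
#' @return A named list (names = molecule ids) of integer bead indices into
#'   `frame$atoms`, with attribute `"indices"` holding the flat index vector.
#' @export
select_role <- function(frame, map, role) {
  idx <- role_indices(frame, map, role)
  if (!length(idx)) {
    message("select_role: no beads match role '", role, "'")
    out <- structure(list(), names = character())
  } else {
    out <- split(idx, frame$atoms$molecule_id[idx])
  }
  attr(out, "indices") <- idx
  out
}
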