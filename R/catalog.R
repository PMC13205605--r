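#' Read a ferroptosis regulator catalog
#'
#' The catalog maps gene symbols to their ferroptosis role: `driver` (promotes
#' ferroptosis) or `suppressor` (inhibits it), in the style of the FerrDb
#' annotation. Genes annotated with both roles are excluded — the signed FR20
#' weighting is undefined for them — and the exclusion is reported.
#'
#' @param path TSV with columns `gene` and `role`.
#' @param source_label Free-text provenance stored on the result.
#' @param drop_other_roles If `TRUE`, rows whose role is neither `driver` nor
#'   `suppressor` (e.g. a "marker" category) are dropped with a message;
#'   if `FALSE` (default) they are an error.
#' @return A tibble with columns `gene`, `role` and attributes `source_label`
#'   and `dropped_dual` (class `fr20_catalog`).
#' @export
read_catalog <- function(path, source_label = basename(path),
                         drop_other_roles = FALSE) {
  if (!file.exists(path)) abort(sprintf("Catalog file not found: %s", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene", "role") %in% names(tab))) {
    abort("Catalog needs columns `gene` and `role`.")
  }
  regulator_catalog(tab$gene, tab$role, source_label = source_label,
                    drop_other_roles = drop_other_roles)
}

#' Construct a regulator catalog from vectors
#'
#' @param gene Character vector of gene symbols (upper-cased on entry).
#' @param role Matching vector of roles.
#' @inheritParams read_catalog
#' @return A `fr20_catalog` tibble.
#' @export
regulator_catalog <- function(gene, role, source_label = "user",
                              drop_other_roles = FALSE) {
  tab <- tibble::tibble(gene = toupper(as.character(gene)),
                        role = as.character(role))
  bad <- setdiff(unique(tab$role), c("driver", "suppressor"))
  if (length(bad) > 0) {
    if (drop_other_roles) {
      n0 <- nrow(tab)
      tab <- dplyr::filter(tab, .data$role %in% c("driver", "suppressor"))
      inform(sprintf("Dropped %d catalog rows with roles outside driver/suppressor: %s",
                     n0 - nrow(tab), paste(bad, collapse = ", ")))
    } else {
      abort(paste0("Unknown regulator role(s): ", paste(bad, collapse = ", ")))
    }
  }
  tab <- dplyr::distinct(tab)
  dual <- tab |>
    dplyr::count(.data$gene) |>
    dplyr::filter(.data$n > 1) |>
    dplyr::pull(.data$gene)
  if (length(dual) > 0) {
    warn(paste0("Excluding ", length(dual),
                " gene(s) annotated as both driver and suppressor: ",
                paste(head(dual, 10), collapse = ", ")))
    tab <- dplyr::filter(tab, !.data$gene %in% dual)
  }
  if (nrow(tab) == 0) abort("Catalog is empty after filtering.")
  structure(tab, class = c("fr20_catalog", class(tab)),
            source_label = source_label, dropped_dual = dual)
}

#' The packaged 20-gene regulator catalog, with optional decoys
#'
#' Returns the 8 up-regulated ferroptosis suppressors and 12 down-regulated
#' drivers of the packaged resistance signature, optionally padded with decoy
#' regulators (catalog members with no planted dysregulation) whose names
#' match those produced by [simulate_sc()]. This is a working fixture, not a
#' reproduction of the full FerrDb driver/suppressor lists.
#'
#' @param n_decoy_drivers,n_decoy_suppressors Number of decoy entries per role.
#' @return A `fr20_catalog` tibble.
#' @export
packaged_catalog <- function(n_decoy_drivers = 0, n_decoy_suppressors = 0) {
  gene <- c(FR20_UP_SUPPRESSORS, FR20_DOWN_DRIVERS,
            decoy_gene_names("driver", n_decoy_drivers),
            decoy_gene_names("suppressor", n_decoy_suppressors))
  role <- c(rep("suppressor", length(FR20_UP_SUPPRESSORS)),
            rep("driver", length(FR20_DOWN_DRIVERS)),
            rep("driver", n_decoy_drivers),
            rep("suppressor", n_decoy_suppressors))
  regulator_catalog(gene, role, source_label = "packaged FR20 catalog")
}

decoy_gene_names <- function(role, n) {
  if (n == 0) return(character(0))
  sprintf("DECOY%s%03d", ifelse(role == "driver", "DRV", "SUP"), seq_len(n))
}

#' Read and write GMT gene-set files
#'
#' Standard tab-separated GMT: one set per line as
#' `name<TAB>description<TAB>member...`. Members are upper-cased.
#'
#' @param path GMT file path.
#' @return `read_gmt()`: a named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3
  if (any(bad)) abort("GMT records need name, description and >= 1 member.")
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- vapply(fields, `[[`, "", 1)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param description Per-set description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "fr20") {
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- mapply(function(nm, d, members) {
    paste(c(nm, d, members), collapse = "\t")
  }, names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}
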