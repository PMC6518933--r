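#' Read and validate a pond table
#'
#' A pond table has one row per pond with projected planar coordinates
#' (metres), per-epoch surface area (ha) and annual-mean conductivity
#' (mS/cm), and extant/sampled flags per epoch. Empty numeric cells mean
#' "absent" (e.g. a pond that no longer existed in 2010 has no
#' `area_2010`), never zero.
#'
#' @param path path to a CSV file with columns `pond_id`, `x`, `y`,
#'   `area_1957`, `area_2010`, `cond_1957`, `cond_2010`, `extant_1957`,
#'   `extant_2010`, `sampled_1957`, `sampled_2010`.
#' @return a `pond_table` data frame.
#' @export
read_pond_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_pond_table(df)
}

#' Validate a data frame as a pond table
#'
#' @param df data frame with the columns described in [read_pond_table()].
#' @return the validated data frame with class `pond_table`.
#' @export
as_pond_table <- function(df) {
  required <- c(
    "pond_id", "x", "y", "area_1957", "area_2010", "cond_1957", "cond_2010",
    "extant_1957", "extant_2010", "sampled_1957", "sampled_2010"
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("pond table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df$pond_id <- as.character(df$pond_id)
  if (anyDuplicated(df$pond_id)) {
    dup <- unique(df$pond_id[duplicated(df$pond_id)])
    stop("duplicate pond_id: ", paste(dup, collapse = ", "))
  }
  for (col in c("extant_1957", "extant_2010", "sampled_1957", "sampled_2010")) {
    df[[col]] <- as.logical(df[[col]])
    if (anyNA(df[[col]])) stop("column ", col, " must be TRUE/FALSE with no missing values")
  }
  for (epoch in c("1957", "2010")) {
    smp <- df[[paste0("sampled_", epoch)]]
    ext <- df[[paste0("extant_", epoch)]]
    bad <- smp & !ext
    if (any(bad)) {
      stop("pond(s) sampled but not extant in ", epoch, ": ",
           paste(df$pond_id[bad], collapse = ", "))
    }
  }
  for (col in c("x", "y", "area_1957", "area_2010", "cond_1957", "cond_2010")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if (anyNA(df$x) || anyNA(df$y)) stop("coordinates x, y must be present for every pond")
  for (col in c("area_1957", "area_2010", "cond_1957", "cond_2010")) {
    bad <- !is.na(df[[col]]) & df[[col]] <= 0
    if (any(bad)) {
      stop("non-positive ", col, " for pond_id: ",
           paste(df$pond_id[bad], collapse = ", "))
    }
  }
  class(df) <- c("pond_table", "data.frame")
  df
}

#' Write a pond table to CSV
#'
#' Inverse of [read_pond_table()]: absent values are written as empty cells.
#'
#' @param ponds a `pond_table`.
#' @param path output CSV path.
#' @export
write_pond_table <- function(ponds, path) {
  utils::write.csv(as.data.frame(ponds), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Construct a site-by-species incidence matrix
#'
#' @param incidence binary matrix (sites in rows, species in columns) with
#'   row names = site ids and column names = species ids.
#' @param epoch epoch label, e.g. `"1957"`.
#' @param allow_empty_species keep all-zero species columns? Default `FALSE`
#'   (they are rejected, since a species that occurs nowhere carries no
#'   information for incidence-based analyses).
#' @return an `occurrence_matrix`: a binary integer matrix with an `epoch`
#'   attribute.
#' @export
occurrence_matrix <- function(incidence, epoch, allow_empty_species = FALSE) {
  m <- as.matrix(incidence)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("incidence matrix needs site row names and species column names")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate site ids")
  if (anyDuplicated(colnames(m))) stop("duplicate species ids")
  bad <- which(!(m %in% c(0, 1)))
  if (length(bad) > 0) {
    i <- ((bad[1] - 1) %% nrow(m)) + 1
    j <- ((bad[1] - 1) %/% nrow(m)) + 1
    stop("non-binary cell at site '", rownames(m)[i], "', species '",
         colnames(m)[j], "': ", m[bad[1]])
  }
  storage.mode(m) <- "integer"
  if (!allow_empty_species && ncol(m) > 0) {
    empty <- colSums(m) == 0
    if (any(empty)) {
      stop("all-zero species column(s): ", paste(colnames(m)[empty], collapse = ", "))
    }
  }
  structure(m, epoch = as.character(epoch), class = c("occurrence_matrix", class(m)))
}

#' Read a site-by-species incidence matrix from CSV
#'
#' First column `site_id`, remaining columns one per species, cells 0/1.
#'
#' @param path CSV path.
#' @param epoch epoch label attached to the matrix.
#' @param ponds optional `pond_table`; when given, site ids are checked
#'   against it.
#' @return an `occurrence_matrix`.
#' @export
read_occurrence_matrix <- function(path, epoch, ponds = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "site_id") stop("first column must be 'site_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df$site_id)
  occ <- occurrence_matrix(m, epoch)
  if (!is.null(ponds)) {
    unknown <- setdiff(rownames(occ), ponds$pond_id)
    if (length(unknown) > 0) {
      stop("site id(s) not in pond table: ", paste(unknown, collapse = ", "))
    }
  }
  occ
}

#' Write an occurrence matrix to CSV
#'
#' @param occ an `occurrence_matrix`.
#' @param path output CSV path.
#' @export
write_occurrence_matrix <- function(occ, path) {
  df <- data.frame(site_id = rownames(occ), as.data.frame(unclass(occ)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Epoch label of an occurrence matrix
#' @param occ an `occurrence_matrix`.
#' @return the epoch label as a character scalar.
#' @export
occ_epoch <- function(occ) attr(occ, "epoch")

#' Derive species traits from epoch-1 occurrences
#'
#' For each species present in the epoch-1 matrix: occupancy (proportion of
#' sampled epoch-1 sites occupied), habitat preference (arithmetic mean
#' epoch-1 conductivity of occupied sites, the salinity-niche position), the
#' body size looked up from `body_sizes`, and whether the species is absent
#' from the epoch-2 regional list (`extinct_2010`). Transforms (square root
#' of occupancy, log body size) are applied later by the extinction model,
#' not here.
#'
#' @param occ_1957 epoch-1 `occurrence_matrix` (rows = sampled ponds).
#' @param ponds `pond_table` supplying `cond_1957` for every occupied site.
#' @param body_sizes data frame with columns `species_id`, `body_size_mm`.
#' @param regional_2010 character vector: species observed anywhere in epoch 2.
#' @return a `trait_table` data frame with columns `species_id`,
#'   `occupancy_1957`, `body_size`, `preference`, `extinct_2010`.
#' @export
derive_species_traits <- function(occ_1957, ponds, body_sizes, regional_2010) {
  sites <- rownames(occ_1957)
  unknown <- setdiff(sites, ponds$pond_id)
  if (length(unknown) > 0) {
    stop("occurrence sites not in pond table: ", paste(unknown, collapse = ", "))
  }
  cond <- ponds$cond_1957[match(sites, ponds$pond_id)]
  n_occ <- colSums(occ_1957)
  if (any(n_occ == 0)) stop("species with zero occupancy in epoch-1 matrix")
  occupied_cond_ok <- vapply(seq_len(ncol(occ_1957)), function(j) {
    !anyNA(cond[occ_1957[, j] == 1])
  }, logical(1))
  if (!all(occupied_cond_ok)) {
    stop("conductivity missing for occupied sites of species: ",
         paste(colnames(occ_1957)[!occupied_cond_ok], collapse = ", "))
  }
  missing_bs <- setdiff(colnames(occ_1957), body_sizes$species_id)
  if (length(missing_bs) > 0) {
    stop("no body size for species: ", paste(missing_bs, collapse = ", "))
  }
  preference <- vapply(seq_len(ncol(occ_1957)), function(j) {
    mean(cond[occ_1957[, j] == 1])
  }, numeric(1))
  traits <- data.frame(
    species_id = colnames(occ_1957),
    occupancy_1957 = n_occ / nrow(occ_1957),
    body_size = body_sizes$body_size_mm[match(colnames(occ_1957), body_sizes$species_id)],
    preference = preference,
    extinct_2010 = !(colnames(occ_1957) %in% regional_2010),
    row.names = NULL
  )
  if (any(traits$body_size <= 0)) stop("body sizes must be positive")
  class(traits) <- c("trait_table", "data.frame")
  traits
}

#' Serialise a result bundle to JSON
#'
#' Writes a versioned JSON file carrying the results plus the seed and the
#' configuration that produced them, so a run can be reproduced from its
#' output alone.
#'
#' @param results a (possibly nested) list of results.
#' @param path output JSON path.
#' @param seed the master seed used for the run (recorded, not consumed).
#' @param config the configuration list to echo into the file.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, seed = NULL, config = list()) {
  bundle <- list(
    schema_version = "1.0",
    seed = seed,
    config = config,
    results = results
  )
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Read back a result bundle written by [write_results()]
#' @param path JSON path.
#' @return the parsed bundle list.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
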