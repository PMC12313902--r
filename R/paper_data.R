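# Packaged study data: physicochemical properties and degree-based
# descriptors for the 17 bladder-cancer drugs. The descriptor table was
# transcribed with the algebraic identity HZ = F + 2*M2 as a per-row
# cross-check; Axitinib's F cell is absent from the printed source and is
# reconstructed from that identity (F = HZ - 2*M2 = 362), which
# validate_descriptor_table() flags.

.property_names <- c("BP", "EV", "FP", "MR", "SA", "MV", "P")
.reconstructed_cells <- data.frame(
  name = "Axitinib", column = "F",
  note = "reconstructed as HZ - 2*M2",
  stringsAsFactors = FALSE
)

.read_fixture <- function(file, columns) {
  path <- system.file("extdata", file, package = "topoqspr")
  if (path == "") stop("packaged fixture not found: ", file)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(df), c("name", columns)) || nrow(df) != 17L ||
      anyNA(df) || !all(vapply(df[columns], is.numeric, logical(1))))
    stop("fixture corruption: ", file, " does not match its expected layout")
  df
}

#' Physicochemical properties of the 17 bladder-cancer drugs
#'
#' Boiling point (BP), enthalpy of vaporization (EV), flash point (FP),
#' molar refractivity (MR), polar surface area (SA), molar volume (MV) and
#' polarizability (P). The source states no units; the pipeline treats them
#' as consistent arbitrary units.
#'
#' @return data frame with columns `name`, `BP`, `EV`, `FP`, `MR`, `SA`,
#'   `MV`, `P`; 17 rows in the study's order (Lenalidomide first,
#'   Gemcitabine last).
#' @export
drug_properties <- function() {
  .read_fixture("bladder_properties.csv", .property_names)
}

#' Degree-based topological descriptors of the 17 bladder-cancer drugs
#'
#' The ten index values per drug. Every row satisfies `HZ = F + 2*M2`
#' within print rounding; Axitinib's `F` is reconstructed from that
#' identity (see [validate_descriptor_table()]).
#'
#' @return data frame with columns `name` and the ten indices of
#'   [index_names()]; 17 rows.
#' @export
drug_descriptors <- function() {
  .read_fixture("bladder_descriptors.csv", index_names())
}

#' Full drug table: properties joined with descriptors
#'
#' @return data frame of 17 rows with `name`, the seven property columns and
#'   the ten descriptor columns.
#' @examples
#' d <- load_drug_table()
#' d[d$name == "Lenalidomide", c("BP", "M1", "HZ")]
#' @export
load_drug_table <- function() {
  merge(drug_properties(), drug_descriptors(), by = "name", sort = FALSE)
}

#' Edge partition of Lenalidomide's molecular graph
#'
#' The worked example of the study: E(1,3) = 4, E(2,2) = 3, E(2,3) = 8,
#' E(3,3) = 6, i.e. 21 edges in total. [topo_indices()] on this partition
#' reproduces the Lenalidomide descriptor row exactly.
#'
#' @return an `edge_partition`.
#' @export
lenalidomide_partition <- function() {
  as_edge_partition(c("1-3" = 4, "2-2" = 3, "2-3" = 8, "3-3" = 6))
}

#' Integrity report for the packaged descriptor table
#'
#' Checks, per drug, that all descriptor values are strictly positive and
#' that the hyper-Zagreb identity `HZ = F + 2*M2` holds within print
#' rounding (absolute gap at most 1, the slack implied by 4-decimal table
#' printing), and lists reconstructed cells. Reports rather than raises.
#'
#' @param descriptors descriptor table, by default [drug_descriptors()].
#' @param tol allowed absolute gap in the identity check.
#' @return data frame with one row per drug: `name`, `hz_gap`
#'   (HZ - F - 2*M2), `identity_ok`, `positive_ok`, `reconstructed` (comma
#'   separated reconstructed columns, `""` if none) and `pass`.
#' @export
validate_descriptor_table <- function(descriptors = drug_descriptors(), tol = 1) {
  idx <- descriptors[index_names()]
  gap <- descriptors$HZ - descriptors$F - 2 * descriptors$M2
  rec <- vapply(descriptors$name, function(nm) {
    paste(.reconstructed_cells$column[.reconstructed_cells$name == nm],
          collapse = ",")
  }, "")
  out <- data.frame(
    name = descriptors$name,
    hz_gap = gap,
    identity_ok = abs(gap) <= tol,
    positive_ok = apply(idx > 0, 1L, all),
    reconstructed = unname(rec),
    stringsAsFactors = FALSE
  )
  out$pass <- out$identity_ok & out$positive_ok
  out
}
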