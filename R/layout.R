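# Biolog EcoMicroplate substrate layout.

# Block map of the standard EcoPlate: 32 wells (8 rows x 4 columns) repeated
# as three replicate blocks at column offsets 0, 4 and 8. Row-major well
# indexing over the full 96-well plate: A1 = 0, A2 = 1, ..., B1 = 12, H12 = 95.
.eco_block <- tibble::tribble(
  ~row, ~col, ~substrate_id, ~guild,
  "A", 1L, "water",                        NA_character_,
  "A", 2L, "beta-methyl-D-glucoside",      "carbohydrate",
  "A", 3L, "D-galactonic acid g-lactone",  "ester",
  "A", 4L, "L-arginine",                   "amino_acid",
  "B", 1L, "pyruvic acid methyl ester",    "ester",
  "B", 2L, "D-xylose",                     "carbohydrate",
  "B", 3L, "D-galacturonic acid",          "carboxylic_acid",
  "B", 4L, "L-asparagine",                 "amino_acid",
  "C", 1L, "Tween 40",                     "ester",
  "C", 2L, "i-erythritol",                 "carbohydrate",
  "C", 3L, "2-hydroxybenzoic acid",        "carboxylic_acid",
  "C", 4L, "L-phenylalanine",              "amino_acid",
  "D", 1L, "Tween 80",                     "ester",
  "D", 2L, "D-mannitol",                   "alcohol",
  "D", 3L, "4-hydroxybenzoic acid",        "carboxylic_acid",
  "D", 4L, "L-serine",                     "amino_acid",
  "E", 1L, "alpha-cyclodextrin",           "carbohydrate",
  "E", 2L, "N-acetyl-D-glucosamine",       "carbohydrate",
  "E", 3L, "gamma-hydroxybutyric acid",    "carboxylic_acid",
  "E", 4L, "L-threonine",                  "amino_acid",
  "F", 1L, "glycogen",                     "carbohydrate",
  "F", 2L, "D-glucosaminic acid",          "carboxylic_acid",
  "F", 3L, "itaconic acid",                "carboxylic_acid",
  "F", 4L, "glycyl-L-glutamic acid",       "amino_acid",
  "G", 1L, "D-cellobiose",                 "carbohydrate",
  "G", 2L, "glucose-1-phosphate",          "carbohydrate",
  "G", 3L, "alpha-ketobutyric acid",       "carboxylic_acid",
  "G", 4L, "phenylethylamine",             "amine",
  "H", 1L, "alpha-D-lactose",              "carbohydrate",
  "H", 2L, "D,L-alpha-glycerol phosphate", "carbohydrate",
  "H", 3L, "D-malic acid",                 "carboxylic_acid",
  "H", 4L, "putrescine",                   "amine"
)

#' EcoPlate guild names
#'
#' The six substrate guilds of the standard 31-substrate EcoPlate.
#' @export
eco_guilds <- c("carbohydrate", "amino_acid", "amine", "ester",
                "carboxylic_acid", "alcohol")

#' Convert well labels to 0-based row-major indices
#'
#' Accepts labels `"A1".."H12"` (rows A-H, columns 1-12; `A1 = 0`,
#' `B1 = 12`) or integers already in `0:95`.
#'
#' @param wells character or integer vector of well identifiers.
#' @return integer vector of 0-based well indices.
#' @export
#' @examples
#' well_index(c("A1", "B1", "H12"))
well_index <- function(wells) {
  if (is.numeric(wells)) {
    idx <- as.integer(wells)
  } else {
    wells <- toupper(trimws(as.character(wells)))
    numeric_like <- grepl("^[0-9]+$", wells)
    idx <- integer(length(wells))
    idx[numeric_like] <- as.integer(wells[numeric_like])
    lab <- wells[!numeric_like]
    if (length(lab)) {
      ok <- grepl("^[A-H](1[0-2]|[1-9])$", lab)
      if (any(!ok)) {
        abort(paste0("Invalid well label(s): ",
                     paste(unique(lab[!ok]), collapse = ", ")))
      }
      row <- match(substr(lab, 1, 1), LETTERS[1:8]) - 1L
      col <- as.integer(substring(lab, 2)) - 1L
      idx[!numeric_like] <- row * 12L + col
    }
  }
  if (any(is.na(idx) | idx < 0L | idx > 95L)) {
    abort("Well indices must lie in 0..95 (labels A1..H12).")
  }
  idx
}

#' Standard Biolog EcoPlate layout
#'
#' The built-in layout of the 96-well EcoPlate: 31 carbon substrates in six
#' guilds plus a water control, each in triplicate (replicate blocks at
#' column offsets 0, 4, 8).
#'
#' @return A tibble with columns `substrate_id`, `guild`, `wells` (list of
#'   0-based well indices), `is_control`.
#' @export
#' @examples
#' eco_layout()
eco_layout <- function() {
  row_i <- match(.eco_block$row, LETTERS[1:8]) - 1L
  base <- row_i * 12L + (.eco_block$col - 1L)
  layout <- tibble(
    substrate_id = .eco_block$substrate_id,
    guild = .eco_block$guild,
    wells = lapply(base, function(b) c(b, b + 4L, b + 8L)),
    is_control = .eco_block$substrate_id == "water"
  )
  validate_layout(layout)
}

#' Read a plate layout file
#'
#' Layout files are TSV with columns `substrate_id`, `guild`, `wells`
#' (semicolon-separated well labels) and `is_control`.
#'
#' @param path path to the layout TSV.
#' @return a validated layout tibble as from [eco_layout()].
#' @export
read_layout <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c("substrate_id", "guild", "wells", "is_control")
  if (!all(need %in% names(raw))) {
    abort(paste("Layout file must have columns:", paste(need, collapse = ", ")))
  }
  layout <- tibble(
    substrate_id = raw$substrate_id,
    guild = ifelse(raw$guild %in% c("", "NA"), NA_character_, raw$guild),
    wells = lapply(strsplit(raw$wells, ";", fixed = TRUE), well_index),
    is_control = tolower(raw$is_control) %in% c("true", "t", "1", "yes")
  )
  validate_layout(layout)
}

#' Validate a substrate layout
#'
#' Checks the EcoPlate layout invariants: exactly one control substrate,
#' 0-based well indices used at most once, at least one well per substrate,
#' control replicated as often as the substrates, and known guild names.
#'
#' @param layout a layout tibble (see [eco_layout()]).
#' @return the layout, invisibly usable, after validation.
#' @export
validate_layout <- function(layout) {
  stopifnot(is.data.frame(layout))
  if (sum(layout$is_control) != 1) {
    abort("Layout must contain exactly one control substrate.")
  }
  if (anyDuplicated(layout$substrate_id)) {
    abort("Duplicate substrate ids in layout.")
  }
  all_wells <- unlist(layout$wells)
  if (any(all_wells < 0 | all_wells > 95)) abort("Well indices out of 0..95.")
  if (anyDuplicated(all_wells)) abort("A well index appears more than once.")
  if (any(lengths(layout$wells) < 1)) abort("Each substrate needs >= 1 well.")
  n_ctl <- lengths(layout$wells)[layout$is_control]
  n_sub <- lengths(layout$wells)[!layout$is_control]
  if (length(unique(c(n_ctl, n_sub))) != 1) {
    warn("Control and substrate replicate counts differ.")
  }
  bad_guild <- !is.na(layout$guild) & !(layout$guild %in% eco_guilds)
  if (any(bad_guild)) {
    abort(paste("Unknown guild(s):",
                paste(unique(layout$guild[bad_guild]), collapse = ", ")))
  }
  layout
}
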