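# Shorthand lipid nomenclature parsing (LIPID MAPS style, tolerant of the
# dialect variants seen in exported peak tables).

lipid_class_vocab <- c("Cer", "CE", "DG", "LPC", "PC", "PE", "PI", "SM", "TG")

# One acyl/sphingoid chain token: optional leading prefix (d/e/p before or
# after the numbers), carbons, separator ':' or '_', double bonds.
parse_chain_token <- function(tok, raw_name) {
  m <- regmatches(tok, regexec("^([dep]?)(\\d+)[:_](\\d+)([dep]?)$", tok))[[1]]
  if (length(m) == 0) {
    abort(sprintf("Malformed chain token '%s' in lipid name '%s'.", tok, raw_name))
  }
  prefix <- if (nzchar(m[2])) m[2] else if (nzchar(m[5])) m[5] else "none"
  list(carbons = as.integer(m[3]), double_bonds = as.integer(m[4]), prefix = prefix)
}

#' Parse shorthand lipid names
#'
#' Parses names like `TG(18:0/17:0/18:0)`, `Cer(d17:1/24:1)`,
#' `TG(18:1_17:1_22:6)` or `LPC(18:1e)` into class, acyl chains and totals.
#' Both the `carbons:double_bonds` and `carbons_double_bonds` dialects are
#' accepted, chains may be separated by `/` or `_`, and the chain prefixes
#' `d` (sphingoid base), `e` (ether) and `p` (plasmalogen) are captured
#' whether written before or after the numbers. Bare class-prefixed forms
#' such as `TG18:1_17:1_22:6` (no parentheses) are also accepted.
#'
#' @param raw_name Character vector of shorthand names.
#' @return A tibble with one row per input name: `raw_name`, `lipid_class`,
#'   `n_chains`, `total_carbons`, `total_double_bonds`, `chain_separator`,
#'   and a list-column `chains` of per-chain tibbles
#'   (`carbons`, `double_bonds`, `prefix`).
#' @examples
#' parse_lipid_name(c("TG(18:0/17:0/18:0)", "Cer(d17:1/24:1)", "LPC(18:1e)"))
#' @export
parse_lipid_name <- function(raw_name) {
  if (length(raw_name) == 0 || any(!nzchar(raw_name)) || any(is.na(raw_name))) {
    abort("`raw_name` must be non-empty strings.")
  }
  purrr::map_dfr(raw_name, parse_one_lipid)
}

parse_one_lipid <- function(nm) {
  s <- gsub("\\s+", "", nm)
  m <- regmatches(s, regexec("^([A-Za-z]+)\\((.+)\\)$", s))[[1]]
  if (length(m)) {
    cls <- m[2]; body <- m[3]
  } else {
    # bare dialect: class token immediately followed by the chains
    m2 <- regmatches(s, regexec("^([A-Za-z]+?)([dep]?\\d.*)$", s))[[1]]
    if (!length(m2)) abort(sprintf("Cannot parse lipid name '%s'.", nm))
    cls <- m2[2]; body <- m2[3]
  }
  if (!cls %in% lipid_class_vocab) {
    abort(sprintf("Unknown lipid class token '%s' in name '%s'.", cls, nm))
  }
  if (grepl("/", body, fixed = TRUE)) {
    sep <- "/"
    toks <- strsplit(body, "/", fixed = TRUE)[[1]]
  } else {
    # '_' separates chains when each piece still holds a ':' pair; otherwise
    # '_' is the carbon-double-bond separator of a single chain
    pieces <- strsplit(body, "_", fixed = TRUE)[[1]]
    if (length(pieces) > 1 && all(grepl(":", pieces))) {
      sep <- "_"; toks <- pieces
    } else if (length(pieces) %% 2 == 0 && !any(grepl(":", pieces))) {
      # fully underscored dialect: c1_d1_c2_d2_...
      sep <- "_"
      idx <- seq(1, length(pieces), by = 2)
      toks <- paste(pieces[idx], pieces[idx + 1], sep = "_")
    } else {
      sep <- "/"; toks <- body
    }
  }
  chains <- purrr::map(toks, parse_chain_token, raw_name = nm)
  chain_tbl <- tibble::tibble(
    carbons = vapply(chains, `[[`, integer(1), "carbons"),
    double_bonds = vapply(chains, `[[`, integer(1), "double_bonds"),
    prefix = vapply(chains, `[[`, character(1), "prefix")
  )
  tibble::tibble(
    raw_name = nm,
    lipid_class = cls,
    n_chains = nrow(chain_tbl),
    total_carbons = sum(chain_tbl$carbons),
    total_double_bonds = sum(chain_tbl$double_bonds),
    chain_separator = sep,
    chains = list(chain_tbl)
  )
}

#' Format a parsed lipid back to shorthand
#'
#' Inverse of [parse_lipid_name()]; formatting then re-parsing round-trips to
#' an identical parse.
#'
#' @param species One row of the tibble returned by [parse_lipid_name()] (or
#'   the whole tibble, formatted row-wise).
#' @return Character vector of shorthand names.
#' @export
format_lipid_name <- function(species) {
  purrr::pmap_chr(
    list(species$lipid_class, species$chains, species$chain_separator),
    function(cls, ch, sep) {
      toks <- ifelse(ch$prefix == "none",
                     sprintf("%d:%d", ch$carbons, ch$double_bonds),
                     sprintf("%s%d:%d", ch$prefix, ch$carbons, ch$double_bonds))
      sprintf("%s(%s)", cls, paste(toks, collapse = sep))
    })
}
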