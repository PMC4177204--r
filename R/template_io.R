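# Curation-template I/O.
#
# One template row = one (vaccine, adverse event, age group) observation taken
# from a package insert's "Adverse Reactions" section. The ten columns follow
# the curation template: vaccine name, vaccine VO id, VAE location,
# VAE name as printed in the insert, VAE name in the AE ontology, its OAE id,
# age category, age-in-years expression, occurrence, and the citation.

TEMPLATE_COLUMNS <- c(
  "vaccine_name", "vaccine_vo_id", "vae_location", "vae_name_insert",
  "vae_name_oae", "oae_id", "age_category", "age_years", "vae_occurrence",
  "reference"
)

AGE_CATEGORIES <- c("child", "adult", "senior", "child-adult")
VAE_LOCATIONS <- c("injection-site", "systemic")

#' Read a curation-template CSV
#'
#' @param path Path to a UTF-8 CSV with exactly the ten template columns:
#'   `r paste(TEMPLATE_COLUMNS, collapse = ", ")`.
#' @return A data frame of template records, one per data row, in file order.
#'   Blank lines are skipped.
#' @export
read_template <- function(path) {
  if (!file.exists(path))
    vaekb_abort("schema", sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        blank.lines.skip = TRUE, colClasses = "character")
  missing <- setdiff(TEMPLATE_COLUMNS, names(df))
  extra <- setdiff(names(df), TEMPLATE_COLUMNS)
  if (length(missing) || length(extra))
    vaekb_abort("schema",
                sprintf("template schema mismatch; missing: [%s], extra: [%s]",
                        paste(missing, collapse = ", "),
                        paste(extra, collapse = ", ")),
                missing = missing, extra = extra)
  df <- df[TEMPLATE_COLUMNS]
  # drop fully blank rows
  blank <- apply(df == "" | is.na(df), 1L, all)
  df <- df[!blank, , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df)) validate_records(df)
  df
}

#' Write template records back to CSV
#' @param records Template record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_template <- function(records, path) {
  utils::write.csv(records[TEMPLATE_COLUMNS], path,
                   row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

# row-level validation; row numbers refer to the record data frame
validate_records <- function(df) {
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    problems <- character()
    if (!is_term_id(r$vaccine_vo_id))
      problems <- c(problems, sprintf("bad vaccine_vo_id '%s'", r$vaccine_vo_id))
    if (!is_term_id(r$oae_id))
      problems <- c(problems, sprintf("bad oae_id '%s'", r$oae_id))
    if (!r$vae_location %in% VAE_LOCATIONS)
      problems <- c(problems, sprintf("bad vae_location '%s'", r$vae_location))
    if (!r$age_category %in% AGE_CATEGORIES)
      problems <- c(problems, sprintf("bad age_category '%s'", r$age_category))
    if (length(problems))
      vaekb_abort("row", sprintf("row %d: %s", i,
                                 paste(problems, collapse = "; ")),
                  row = i)
    # these raise parse/range conditions with their own class
    iv <- withCallingHandlers(
      parse_age_years(r$age_years),
      vaekb_error = function(e)
        vaekb_abort("row", sprintf("row %d: %s", i, conditionMessage(e)),
                    row = i)
    )
    withCallingHandlers(
      parse_occurrence(r$vae_occurrence),
      vaekb_error = function(e)
        vaekb_abort("row", sprintf("row %d: %s", i, conditionMessage(e)),
                    row = i)
    )
    declared <- r$age_category
    computed <- categorize_age(iv)
    # senior intervals sit inside the adult range; curators may record either
    ok <- declared == computed ||
      (declared == "adult" && computed == "senior") ||
      (declared == "senior" && computed == "adult")
    if (!ok)
      vaekb_warn("category_mismatch",
                 sprintf("row %d: declared age_category '%s' but '%s' computed from '%s'",
                         i, declared, computed, r$age_years))
  }
  invisible(df)
}

#' Parse an age-range expression into an interval in years
#'
#' Grammar: `<num>` (a single age, widened to `[num, num + 1]`),
#' `<num>-<num>`, `<num>+` (open-ended upper bound), where each `<num>` may
#' carry a `mo` suffix meaning months (divided by 12). Intervals are closed;
#' an open upper bound is represented as `Inf`.
#'
#' @param expr Age expression, e.g. `"18-40"`, `"65+"`, `"6mo-35mo"`, `"2"`.
#' @return A list with numeric `min` and `max` (years; `max` may be `Inf`).
#' @export
parse_age_years <- function(expr) {
  s <- gsub(" ", "", expr)
  num <- function(tok) {
    m <- regmatches(tok, regexec("^([0-9]+(?:\\.[0-9]+)?)(mo)?$", tok))[[1]]
    if (!length(m))
      vaekb_abort("parse", sprintf("unparseable age token '%s' in '%s'", tok, expr))
    v <- as.numeric(m[2])
    if (identical(m[3], "mo")) v <- v / 12
    v
  }
  if (grepl("^[^-]+\\+$", s)) {
    lo <- num(sub("\\+$", "", s))
    iv <- list(min = lo, max = Inf)
  } else if (grepl("-", s, fixed = TRUE)) {
    parts <- strsplit(s, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      vaekb_abort("parse", sprintf("unparseable age range '%s'", expr))
    iv <- list(min = num(parts[1]), max = num(parts[2]))
  } else {
    lo <- num(s)
    iv <- list(min = lo, max = lo + 1)
  }
  if (iv$min < 0)
    vaekb_abort("range", sprintf("negative age in '%s'", expr))
  if (is.finite(iv$max) && iv$min >= iv$max)
    vaekb_abort("range", sprintf("empty age interval '%s'", expr))
  iv
}

#' Parse an occurrence expression into a fraction
#'
#' Accepts `"<num>%"` (percent) or a bare decimal already in `[0, 1]`.
#' Occurrences are stored internally as fractions; reports render percents.
#'
#' @param expr e.g. `"97.5%"` or `"0.31"`.
#' @return Numeric fraction in `[0, 1]`.
#' @export
parse_occurrence <- function(expr) {
  s <- gsub(" ", "", expr)
  pct <- grepl("%$", s)
  body <- sub("%$", "", s)
  if (!grepl("^[0-9]+(\\.[0-9]+)?$", body))
    vaekb_abort("parse", sprintf("unparseable occurrence '%s'", expr))
  v <- as.numeric(body)
  if (pct) {
    if (v > 100)
      vaekb_abort("range", sprintf("occurrence above 100%%: '%s'", expr))
    v <- v / 100
  } else if (v > 1) {
    vaekb_abort("range",
                sprintf("bare occurrence must lie in [0,1]: '%s'", expr))
  }
  v
}

#' Age category of an interval
#'
#' Categories: `child` when the interval lies entirely at or under 18 years,
#' `senior` when entirely at or above 65, `adult` when entirely at or above 18
#' (starting under 65), and `child-adult` when the interval straddles 18.
#'
#' @param interval A list with `min`/`max` as from [parse_age_years()].
#' @return One of `"child"`, `"adult"`, `"senior"`, `"child-adult"`.
#' @export
categorize_age <- function(interval) {
  if (interval$max <= 18) return("child")
  if (interval$min >= 65) return("senior")
  if (interval$min >= 18) return("adult")
  "child-adult"
}

#' Merge template records into vaccine-AE associations
#'
#' Rows sharing `(vaccine_vo_id, oae_id)` become one association whose
#' `groups` list holds each row's (age interval, category, occurrence), sorted
#' by ascending minimum age. Intervals within one association must not overlap
#' (sharing an endpoint is allowed) and the location must agree across rows.
#'
#' @param records Validated template record data frame.
#' @return A list of association records, each with fields `vaccine`,
#'   `vaccine_label`, `ae`, `ae_label`, `location`, `groups`, `reference`.
#' @export
records_to_associations <- function(records) {
  if (!nrow(records)) return(list())
  key <- paste(records$vaccine_vo_id, records$oae_id, sep = "|")
  out <- list()
  for (k in unique(key)) {
    rs <- records[key == k, , drop = FALSE]
    if (length(unique(rs$vae_location)) != 1L)
      vaekb_abort("conflict",
                  sprintf("conflicting VAE location for %s / %s",
                          rs$vaccine_vo_id[1], rs$oae_id[1]))
    groups <- lapply(seq_len(nrow(rs)), function(i) {
      iv <- parse_age_years(rs$age_years[i])
      list(min = iv$min, max = iv$max,
           category = rs$age_category[i],
           occurrence = parse_occurrence(rs$vae_occurrence[i]))
    })
    groups <- groups[order(vapply(groups, function(g) g$min, numeric(1)))]
    if (length(groups) > 1L) {
      for (i in seq_len(length(groups) - 1L)) {
        a <- groups[[i]]; b <- groups[[i + 1L]]
        if (max(a$min, b$min) < min(a$max, b$max))
          vaekb_abort("overlap",
                      sprintf("overlapping age intervals for %s / %s",
                              rs$vaccine_vo_id[1], rs$oae_id[1]))
      }
    }
    out[[k]] <- list(
      vaccine = rs$vaccine_vo_id[1],
      vaccine_label = rs$vaccine_name[1],
      ae = rs$oae_id[1],
      ae_label = rs$vae_name_oae[1],
      location = rs$vae_location[1],
      groups = groups,
      reference = rs$reference[1]
    )
  }
  unname(out)
}
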