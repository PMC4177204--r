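# Bundled fixtures and the synthetic record generator.
#
# Fixtures transcribe the structure of the published examples (AE lists, id
# columns, printed count tables); occurrence values and age groups that are
# only legible from figure screenshots are synthetic and flagged as such in
# inst/extdata/README.md. The generator emits arbitrary-scale
# package-insert-style record sets with exact ground-truth bookkeeping.

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "vaekb")
  if (!nzchar(p)) p <- file.path("inst", "extdata", file) # pre-install fallback
  p
}

#' Bundled mini seed-term table
#'
#' A mini-OAE/VO class hierarchy: the top-10 reported adverse events with
#' their published OAE ids, their parent groupings, an `'injection site'`
#' anatomical term, and the `'adverse event'` / `'vaccine'` roots. Enough to
#' compile every bundled fixture.
#'
#' @return Seed-term data frame (`id,label,parent_ids,source`).
#' @export
vaekb_seed_terms <- function() {
  read_seed_terms(extdata_path("seed_terms.csv"))
}

#' Load a bundled fixture
#'
#' * `"afluria"` — template records for the nine Afluria adverse-event types
#'   (injection-site pain carries three age groups).
#' * `"table2"` — template records expanding the printed top-10
#'   vaccine-variety counts into per-AE rows (attribute `counts` holds the
#'   printed table).
#' * `"table3"` — template records for a 63-vaccine world whose per-AE vaccine
#'   counts equal the printed top-10 frequency table (attribute `counts`).
#' * `"figure4"` — a `vae_kb` with the asserted mini-OAE hierarchy of the
#'   top-10 AEs plus the definitional axiom for
#'   `'injection-site adverse event'` (`'adverse event' and 'occurs in' some
#'   'injection site'`), ready for [classify_kb()].
#' * `"typhim_vi"` — template records whose maximal occurrence is the
#'   Typhim Vi injection-site tenderness entry (97.5%, ages 18–40).
#' * `"table1"` — a `vae_kb` populated with placeholder classes so that the
#'   per-source class counts equal the published term-statistics table
#'   (class-column total 1189).
#'
#' @param name Fixture name.
#' @return Template records (data frame) or a `vae_kb` (for `"figure4"` and
#'   `"table1"`).
#' @export
load_fixture <- function(name) {
  switch(name,
    afluria = read_template(extdata_path("afluria.csv")),
    typhim_vi = read_template(extdata_path("typhim_vi.csv")),
    table2 = fixture_table2(),
    table3 = fixture_table3(),
    figure4 = fixture_figure4(),
    table1 = fixture_table1(),
    vaekb_abort("fixture_not_found", sprintf("unknown fixture '%s'", name))
  )
}

# deterministic synthetic occurrence in (0, 0.6]; varies by row index
synth_occurrence_text <- function(i) {
  sprintf("%.1f%%", 1 + ((i * 7) %% 55))
}

# the 10 + filler AE vocabulary used to expand printed count tables
fixture_ae_vocab <- function() {
  seed <- vaekb_seed_terms()
  top10 <- c("OAE_0000369", "OAE_0000377", "OAE_0000361", "OAE_0001139",
             "OAE_0001546", "OAE_0001105", "OAE_0000390", "OAE_0000644",
             "OAE_0000375", "OAE_0000034")
  extra <- seed$id[grepl("^OAE_09", seed$id)]
  ids <- c(top10, sort(extra))
  data.frame(id = ids,
             label = vapply(ids, function(i) seed$label[seed$id == i],
                            character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

make_records <- function(vaccine_name, vo_id, ae_ids, ae_labels, row_offset = 0L) {
  n <- length(ae_ids)
  data.frame(
    vaccine_name = rep(vaccine_name, n),
    vaccine_vo_id = rep(vo_id, n),
    vae_location = ifelse(grepl("injection-site", ae_labels),
                          "injection-site", "systemic"),
    vae_name_insert = ae_label_stem(ae_labels),
    vae_name_oae = ae_labels,
    oae_id = ae_ids,
    age_category = rep("adult", n),
    age_years = rep("18-64", n),
    vae_occurrence = vapply(seq_len(n) + row_offset, synth_occurrence_text,
                            character(1)),
    reference = rep(sprintf("%s package insert (synthetic expansion)",
                            vaccine_name), n),
    stringsAsFactors = FALSE
  )
}

fixture_table2 <- function() {
  counts <- utils::read.csv(extdata_path("table2_counts.csv"),
                            stringsAsFactors = FALSE,
                            colClasses = c("character", "character", "integer"))
  vocab <- fixture_ae_vocab()
  if (max(counts$n_vae) > nrow(vocab))
    vaekb_abort("config", "AE vocabulary smaller than largest printed count")
  recs <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    k <- counts$n_vae[i]
    make_records(counts$vaccine[i], counts$vo_id[i],
                 vocab$id[seq_len(k)], vocab$label[seq_len(k)],
                 row_offset = i * 3L)
  }))
  rownames(recs) <- NULL
  attr(recs, "counts") <- counts
  recs
}

fixture_table3 <- function() {
  counts <- utils::read.csv(extdata_path("table3_counts.csv"),
                            stringsAsFactors = FALSE,
                            colClasses = c("character", "character",
                                           "integer", "numeric"))
  n_vaccines <- 63L
  vocab <- fixture_ae_vocab()
  filler_id <- vocab$id[11L]; filler_label <- vocab$label[11L]
  recs <- list()
  covered <- logical(n_vaccines)
  for (j in seq_len(nrow(counts))) {
    vaccines <- seq_len(counts$n_vaccines[j])
    covered[vaccines] <- TRUE
    lab <- counts$ae_label[j]
    for (v in vaccines)
      recs[[length(recs) + 1L]] <- make_records(
        sprintf("synthetic vaccine %02d", v),
        term_id("VO", 100000L + v),
        counts$oae_id[j], lab, row_offset = j + v)
  }
  for (v in which(!covered))
    recs[[length(recs) + 1L]] <- make_records(
      sprintf("synthetic vaccine %02d", v),
      term_id("VO", 100000L + v),
      filler_id, filler_label, row_offset = v)
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "counts") <- counts
  attr(out, "n_vaccines") <- n_vaccines
  out
}

fixture_figure4 <- function() {
  kb <- kb_new()
  register_seed_terms(kb, vaekb_seed_terms())
  is_site <- kb_class(kb, "injection site")$id
  # defined class: adverse event occurring in an injection site
  isae <- kb_class(kb, "injection-site adverse event")$id
  kb_set_expression(kb, isae,
                    ce_and(ce_named(kb_class(kb, "adverse event")$id),
                           ce_some(PROP_OCCURS_IN, ce_named(is_site))),
                    style = "equivalent")
  # the single-inheritance rule keeps these asserted under their phenotype
  # parents; the 'occurs in' axiom is what the reasoner picks up
  for (lab in c("injection-site pain AE", "injection-site redness AE"))
    kb_set_expression(kb, kb_class(kb, lab)$id,
                      ce_some(PROP_OCCURS_IN, ce_named(is_site)),
                      style = "subclass")
  kb
}

fixture_table1 <- function() {
  counts <- utils::read.csv(extdata_path("table1_counts.csv"),
                            stringsAsFactors = FALSE,
                            colClasses = c("character", "integer"))
  kb <- kb_new()
  for (i in seq_len(nrow(counts))) {
    src <- counts$source[i]
    n <- counts$n_classes[i]
    if (!n) next
    # OVAE serials 1..5 are the pattern properties; keep class ids clear
    offset <- if (src == "OVAE") 100L else 0L
    for (k in seq_len(n))
      kb_register_class(kb, ontology_class(
        term_id(src, offset + k),
        sprintf("%s placeholder term %d", src, k), source = src))
  }
  kb
}

# ---------------------------------------------------------------------------
# synthetic generator

default_age_schemes <- function() {
  list(
    list(list(min = 0, max = Inf, category = "child-adult")),
    list(list(min = 0, max = 18, category = "child"),
         list(min = 18, max = 65, category = "adult")),
    list(list(min = 0, max = 18, category = "child"),
         list(min = 18, max = 65, category = "adult"),
         list(min = 65, max = Inf, category = "senior")),
    list(list(min = 0, max = 18, category = "child")),
    list(list(min = 18, max = 65, category = "adult"))
  )
}

#' Generator configuration
#'
#' Defaults emulate the curated world: 63 licensed vaccines, an 87-term
#' adverse-event vocabulary, 3–20 AEs per vaccine, age groups drawn from the
#' child/adult/senior/child-adult breakpoints (0, 18, 65), and occurrences
#' drawn from per-category Beta distributions with a planted child-over-adult
#' mean shift of 0.1 (child Beta(2.4, 3.6), mean 0.4; adult/senior
#' Beta(1.8, 4.2), mean 0.3; child-adult Beta(2.1, 3.9), mean 0.35).
#'
#' @param n_vaccines,ae_vocabulary Sizes of the two term pools.
#' @param aes_per_vaccine Integer range `c(lo, hi)` (or a single fixed count).
#' @param age_schemes List of age-group schemes; one is drawn per association.
#' @param beta_params Named list of `c(alpha, beta)` per age category.
#' @param seed Integer seed; same seed and config give identical output.
#' @return A `vae_gen_config` list.
#' @export
generator_config <- function(n_vaccines = 63L, ae_vocabulary = 87L,
                             aes_per_vaccine = c(3L, 20L),
                             age_schemes = default_age_schemes(),
                             beta_params = list(
                               child = c(2.4, 3.6),
                               adult = c(1.8, 4.2),
                               senior = c(1.8, 4.2),
                               `child-adult` = c(2.1, 3.9)),
                             seed = 1L) {
  if (length(aes_per_vaccine) == 1L)
    aes_per_vaccine <- rep(as.integer(aes_per_vaccine), 2L)
  cfg <- list(n_vaccines = as.integer(n_vaccines),
              ae_vocabulary = as.integer(ae_vocabulary),
              aes_per_vaccine = as.integer(aes_per_vaccine),
              age_schemes = age_schemes,
              beta_params = beta_params,
              seed = as.integer(seed))
  if (cfg$n_vaccines < 1L || cfg$ae_vocabulary < 1L)
    vaekb_abort("config", "n_vaccines and ae_vocabulary must be >= 1")
  if (cfg$aes_per_vaccine[2L] > cfg$ae_vocabulary)
    vaekb_abort("config", "aes_per_vaccine exceeds the AE vocabulary size")
  if (cfg$aes_per_vaccine[1L] < 1L ||
      cfg$aes_per_vaccine[1L] > cfg$aes_per_vaccine[2L])
    vaekb_abort("config", "invalid aes_per_vaccine range")
  structure(cfg, class = "vae_gen_config")
}

#' Generate a synthetic record set with ground truth
#'
#' @param config A [generator_config()].
#' @return A list with `records` (template data frame), `truth` (planted
#'   per-vaccine AE counts, per-AE vaccine counts, per-category occurrence
#'   means with `senior` folded into `adult`), and `seed_terms` (a seed table
#'   covering the generated vocabulary, for [compile_kb()]).
#' @export
generate <- function(config = generator_config()) {
  cfg <- config
  vocab_ids <- vapply(seq_len(cfg$ae_vocabulary),
                      function(i) term_id("OAE", 100000L + i), character(1))
  vocab_labels <- sprintf("synthetic AE %04d AE", seq_len(cfg$ae_vocabulary))
  vaccine_ids <- vapply(seq_len(cfg$n_vaccines),
                        function(i) term_id("VO", 100000L + i), character(1))
  vaccine_labels <- sprintf("synthetic vaccine %04d", seq_len(cfg$n_vaccines))

  rows <- withr::with_seed(cfg$seed, {
    out <- list()
    for (v in seq_len(cfg$n_vaccines)) {
      k <- if (cfg$aes_per_vaccine[1L] == cfg$aes_per_vaccine[2L])
        cfg$aes_per_vaccine[1L]
      else sample(cfg$aes_per_vaccine[1L]:cfg$aes_per_vaccine[2L], 1L)
      aes <- sort(sample.int(cfg$ae_vocabulary, k))
      for (j in aes) {
        scheme <- cfg$age_schemes[[sample.int(length(cfg$age_schemes), 1L)]]
        for (g in scheme) {
          p <- cfg$beta_params[[g$category]]
          occ <- round(stats::rbeta(1L, p[1L], p[2L]), 4L)
          age_text <- if (is.infinite(g$max)) sprintf("%s+", format_decimal(g$min))
                      else sprintf("%s-%s", format_decimal(g$min),
                                   format_decimal(g$max))
          out[[length(out) + 1L]] <- data.frame(
            vaccine_name = vaccine_labels[v],
            vaccine_vo_id = vaccine_ids[v],
            vae_location = if (grepl("injection-site", vocab_labels[j]))
              "injection-site" else "systemic",
            vae_name_insert = ae_label_stem(vocab_labels[j]),
            vae_name_oae = vocab_labels[j],
            oae_id = vocab_ids[j],
            age_category = g$category,
            age_years = age_text,
            vae_occurrence = sprintf("%s%%", format_decimal(occ * 100)),
            reference = "synthetic generator",
            stringsAsFactors = FALSE)
        }
      }
    }
    out
  })
  records <- do.call(rbind, rows)
  rownames(records) <- NULL

  # ground truth recomputed from the emitted records so it matches exactly
  key <- paste(records$vaccine_vo_id, records$oae_id, sep = "|")
  pairs <- !duplicated(key)
  per_vaccine <- as.data.frame(table(records$vaccine_vo_id[pairs]),
                               stringsAsFactors = FALSE)
  names(per_vaccine) <- c("vaccine", "n_ae")
  per_ae <- as.data.frame(table(records$oae_id[pairs]),
                          stringsAsFactors = FALSE)
  names(per_ae) <- c("ae", "n_vaccines")
  occ <- vapply(records$vae_occurrence, parse_occurrence, numeric(1))
  cat3 <- ifelse(records$age_category == "senior", "adult",
                 records$age_category)
  category_means <- data.frame(
    category = c("child", "adult", "child-adult"),
    mean_occurrence = vapply(c("child", "adult", "child-adult"), function(l) {
      v <- occ[cat3 == l]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)

  seed_terms <- data.frame(
    id = c("OAE_0000001", vocab_ids, "VO_0000001", vaccine_ids),
    label = c("adverse event", vocab_labels, "vaccine", vaccine_labels),
    parent_ids = c("", rep("OAE_0000001", length(vocab_ids)),
                   "", rep("VO_0000001", length(vaccine_ids))),
    source = c(rep("OAE", length(vocab_ids) + 1L),
               rep("VO", length(vaccine_ids) + 1L)),
    stringsAsFactors = FALSE)

  list(records = records,
       truth = list(per_vaccine = per_vaccine, per_ae = per_ae,
                    category_means = category_means),
       seed_terms = seed_terms)
}
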