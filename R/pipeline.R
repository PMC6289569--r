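# End-to-end pipeline tying the stages together: synthetic pools ->
# products -> preprocessing -> signatures/fingerprints -> matched pools ->
# folding/structure profiles -> motifs -> recombination grid ->
# combinatorics, with one master seed, TSV outputs and a checksum manifest.

#' Default pipeline configuration
#'
#' Returns the full configuration list used by [run_pipeline()]; any subset
#' can be overridden via the `config` argument. All stochastic stages are
#' seeded from the single `seed` entry via a fixed per-stage derivation, so
#' identical configurations reproduce identical outputs byte for byte.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    input_fastq = NULL,
    bait = list(length = 20L, alphabet = "ACGU", n_unique = 1000L,
                redundancy = 100L, constant5 = NULL, blocked5 = FALSE),
    prey = list(length = 20L, alphabet = "ACGU", n_unique = 1000L,
                redundancy = 100L, constant3 = NULL, tail = NULL),
    products = list(n_products = 5000L, junction_bias = list(CN = 8),
                    truncation = list(family = "geometric", prob = 0.25),
                    product_mix = list(`B-P` = 1)),
    quality = list(sub_rate = 0.001, quality = 38L, tail_frac = 0.05,
                   tail_len = 10L, tail_quality = 2L),
    preprocess = list(min_q = 20L, min_fraction = 0.9),
    matched = list(replicates = 3L, n = 300000L),
    fold = list(backend = "internal", max_seqs = 500L, min_loop = 3L),
    motifs = list(window = 10L),
    grid = list(hydrolysis_rates = seq(0.2, 1, by = 0.2),
                ligation_rates = seq(0.2, 1, by = 0.2), replicates = 10L,
                enabled = TRUE),
    combinatorics = list(n_molecules = 1e15, length = 20L, alphabet_size = 4L),
    kinetics = NULL
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys override [default_config()] entries.
#' @return configuration list.
#' @export
load_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

write_tsv_commented <- function(df, path, comment) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline into an output directory
#'
#' Executes the stages in order (pool generation, product synthesis with
#' qualities, preprocessing, length splitting, nucleotide signature,
#' junction fingerprint, matched-pool generation, internal folding and
#' structure-profile comparison, motif scan, recombination delta-D grid,
#' pool combinatorics, optional kinetics fit), writing TSV artifacts, the
#' effective configuration, and a checksum manifest. Re-running with an
#' identical configuration reproduces identical numeric outputs.
#'
#' @param config configuration list (see [default_config()]) or a path to
#'   a YAML file; partial lists are merged over the defaults.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the main in-memory results and the
#'   manifest tibble.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L) config <- load_run_config(config)
  cfg <- merge_config(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  alphabet <- strsplit(cfg$bait$alphabet, "", fixed = TRUE)[[1]]

  bait <- run_stage("makepool", {
    make_pool(pool_spec(length = cfg$bait$length, alphabet = alphabet,
                        n_unique = cfg$bait$n_unique, redundancy = cfg$bait$redundancy,
                        constant5 = cfg$bait$constant5, blocked5 = isTRUE(cfg$bait$blocked5)),
              seed = derive_seed(seed, "bait"))
  })
  prey <- run_stage("makepool", {
    make_pool(pool_spec(length = cfg$prey$length, alphabet = alphabet,
                        n_unique = cfg$prey$n_unique, redundancy = cfg$prey$redundancy,
                        constant3 = cfg$prey$constant3, tail = cfg$prey$tail),
              seed = derive_seed(seed, "prey"))
  })

  products <- run_stage("makeproducts", {
    ps <- product_spec(
      junction_bias = unlist(cfg$products$junction_bias),
      truncation_dist = cfg$products$truncation,
      product_mix = unlist(cfg$products$product_mix),
      n_products = cfg$products$n_products
    )
    make_products(bait, prey, ps, seed = derive_seed(seed, "products"))
  })
  reads <- run_stage("makeproducts", {
    attach_quality(products,
                   error_profile(sub_rate = cfg$quality$sub_rate,
                                 quality = cfg$quality$quality,
                                 tail_frac = cfg$quality$tail_frac,
                                 tail_len = cfg$quality$tail_len,
                                 tail_quality = cfg$quality$tail_quality),
                   seed = derive_seed(seed, "quality"), alphabet = alphabet)
  })
  fastq_path <- file.path(out_dir, "products.fastq")
  write_fastq(reads, fastq_path)
  write_tsv_commented(
    select(products, -"seq"), file.path(out_dir, "truth.tsv"),
    "truth labels: class, bait/prey ids, bait 3'-truncation (nt), junction bond index (1-based)")

  # an external FASTQ can replace the generated reads for preprocessing
  kept <- run_stage("io_formats", {
    read_fastq(cfg$input_fastq %||% fastq_path) |>
      quality_filter(min_q = cfg$preprocess$min_q,
                     min_fraction = cfg$preprocess$min_fraction)
  })
  collapsed <- collapse_reads(kept)
  buckets <- split_by_length(collapsed)
  write_tsv_commented(select(buckets, -"data"),
                      file.path(out_dir, "length_histogram.tsv"),
                      "product size distribution: length (nt), n_records (unique), n_molecules (reads)")

  # dominant length class drives the signature/fingerprint stages
  top <- buckets$data[[which.max(buckets$n_molecules)]]
  top_len <- buckets$length[which.max(buckets$n_molecules)]
  profile <- run_stage("signature", frequency_profile(top, weighted = TRUE,
                                                      alphabet = sort(alphabet)))
  sig <- rgb_signature(profile)
  write_tsv_commented(as_tibble(profile), file.path(out_dir, "frequency_profile.tsv"),
                      sprintf("position-specific nucleotide frequencies, %d-nt class (fractions, rows sum to 1)", top_len))
  write_tsv_commented(sig, file.path(out_dir, "rgb_signature.tsv"),
                      "RGB signature per position (0-255 reals; hex rounded half-up)")

  fp <- run_stage("fingerprint", {
    jx <- products$junction[products$junction > 0 & nchar(products$seq) == top_len]
    junction_fingerprint(top, junction_index = as.integer(stats::median(jx)),
                         alphabet = sort(alphabet))
  })
  write_tsv_commented(as_tibble(fp), file.path(out_dir, "junction_fingerprint.tsv"),
                      "junction dinucleotide table: observed/expected frequencies, log2 enrichment, difference")

  matched <- run_stage("matchedpool", {
    lapply(seq_len(cfg$matched$replicates), function(r) {
      generate_matched_pool(profile, n = cfg$matched$n,
                            seed = derive_seed(seed, "matched", r))
    })
  })

  prod_top <- filter(products, nchar(.data$seq) == top_len)
  fold_res <- run_stage("fold", {
    k <- min(cfg$fold$max_seqs, nrow(prod_top))
    fold_one <- function(seqs) {
      if (identical(cfg$fold$backend, "internal")) {
        vapply(seqs, function(x) nussinov_fold(x, min_loop = cfg$fold$min_loop)$structure,
               character(1), USE.NAMES = FALSE)
      } else {
        external_fold(seqs, cfg$fold$backend)$structure
      }
    }
    list(experimental = fold_one(head(prod_top$seq, k)),
         synthetic = lapply(matched, function(m) fold_one(head(m, k))))
  })
  comparison <- run_stage("structureprofile", {
    compare_structure_profiles(structure_profile(fold_res$experimental),
                               lapply(fold_res$synthetic, structure_profile))
  })
  write_tsv_commented(comparison, file.path(out_dir, "structure_comparison.tsv"),
                      "per-position obp/cbp/unp frequencies: experimental vs matched synthetic pools (fractions)")

  motif_prof <- run_stage("motifs", {
    catalogue <- submotif_catalogue()
    k <- length(fold_res$experimental)
    matches <- bind_rows(map2(fold_res$experimental, head(prod_top$junction, k),
      function(st, j) match_submotifs(st, j, catalogue, window = cfg$motifs$window)))
    if (nrow(matches) == 0) NULL else motif_ligation_profile(matches, catalogue)
  })
  if (!is.null(motif_prof)) {
    write_tsv_commented(as_tibble(motif_prof), file.path(out_dir, "motif_profile.tsv"),
                        "normalized ligation-site frequency per intra-motif bond")
  }

  grid <- NULL
  if (isTRUE(cfg$grid$enabled)) {
    grid <- run_stage("simulate", {
      delta_D_grid(pool_spec(length = cfg$bait$length, alphabet = alphabet,
                             n_unique = cfg$bait$n_unique,
                             redundancy = cfg$bait$redundancy),
                   hydrolysis_rates = cfg$grid$hydrolysis_rates,
                   ligation_rates = cfg$grid$ligation_rates,
                   replicates = cfg$grid$replicates,
                   seed = derive_seed(seed, "grid"))
    })
    write_tsv_commented(as_tibble(grid), file.path(out_dir, "delta_d_grid.tsv"),
                        "mean/sd delta Shannon index (bits) per hydrolysis x ligation rate")
  }

  comb <- run_stage("combinatorics", {
    pool_combinatorics(cfg$combinatorics$n_molecules, cfg$combinatorics$length,
                       cfg$combinatorics$alphabet_size)
  })
  write_tsv_commented(comb, file.path(out_dir, "combinatorics.tsv"),
                      "pool combinatorics: diversity (sequences), redundancy (copies), amount (nmol), binary pairs")

  kin <- NULL
  if (!is.null(cfg$kinetics)) {
    kin <- run_stage("kinetics", {
      fit_ligation_kinetics(cfg$kinetics$timepoints, cfg$kinetics$yields)
    })
    write_tsv_commented(glance(kin), file.path(out_dir, "kinetics_fit.tsv"),
                        "pseudo-first-order fit: k_obs (1/time), plateau (fraction)")
  }

  yaml::write_yaml(cfg, file.path(out_dir, "run_config.yaml"))
  files <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
  manifest <- tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    bytes = file.size(file.path(out_dir, files))
  )
  write_tsv_commented(manifest,
                      file.path(out_dir, "manifest.tsv"),
                      sprintf("pipeline manifest; poolforge %s; seed %d",
                              as.character(utils::packageVersion("poolforge")), seed))
  invisible(list(products = products, profile = profile, fingerprint = fp,
                 comparison = comparison, motif_profile = motif_prof,
                 grid = grid, combinatorics = comb, kinetics = kin,
                 manifest = manifest))
}
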