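# Approximate autosome lengths (Mb); coordinate frame for simulated SNPs,
# LOH events and segments. No reference genome is shipped or required.
CHROM_LENGTHS_MB <- c(
  chr1 = 249, chr2 = 243, chr3 = 198, chr4 = 191, chr5 = 181, chr6 = 171,
  chr7 = 159, chr8 = 146, chr9 = 141, chr10 = 136, chr11 = 135, chr12 = 134,
  chr13 = 115, chr14 = 107, chr15 = 103, chr16 = 90, chr17 = 81, chr18 = 78,
  chr19 = 59, chr20 = 63, chr21 = 48, chr22 = 51
)

# The 15 pancreatic driver genes whose coding regions are fully covered by
# the targeted panel.
DRIVER_GENES_15 <- c(
  "APC", "ATM", "BRAF", "CDKN2A", "CTNNB1", "GNAS", "KRAS", "MAP2K4",
  "PIK3CA", "PTEN", "RNF43", "SMAD4", "STK11", "TGFBR2", "TP53"
)

#' Derive a reproducible substream seed for a named pipeline stage
#'
#' All stochastic stages draw from an independent substream derived from the
#' single run seed, so that adding or reordering stages does not perturb the
#' random numbers other stages see.
#'
#' @param seed Integer master seed.
#' @param stage Character scalar naming the stage (e.g. "loh", "timing").
#' @return An integer seed in [0, 2^31).
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

#' Default pipeline configuration
#'
#' Every threshold used by the pipeline, grouped by stage. Values default to
#' the study's published calling, copy-number, LOH and timing parameters.
#'
#' @param seed Integer master seed governing all stochastic stages.
#' @return A nested list of stage parameter blocks.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    calling = list(
      coverage_floor_fraction = 0.20,
      normal_min_depth = 10L,
      normal_max_vaf = 0.02,
      wes_primary_min_vaf = 0.10,
      wes_primary_min_alt = 5L,
      wes_secondary_min_alt = 2L,
      targeted_min_vaf = 0.05,
      targeted_alt_scale_base = 5L,
      exclude_sites = character()
    ),
    copy_number = list(
      homdel_log2 = -1.25,
      amp_log2 = 1.6,
      focal_max_mb = 3,
      amp_ploidy_mult = 3,
      purity_cut = 0.30,
      ccf_cut = 0.75,
      gc_correct = TRUE
    ),
    loh = list(
      diff_cut = 0.1,
      min_mb = 10,
      min_snps = 20L,
      tier_edges = c(0.1, 0.2),
      merge_window_mb = 5,
      targeted_min_depth = 20L,
      seg_alpha = 0.01,
      seg_perms = 1000L,
      seg_min_width = 5L
    ),
    phylo = list(
      near_miss_margin = 0.20,
      max_leaves = 25L
    ),
    timing = list(
      mu_grid = 1:10,
      chains = 4L,
      iters = 20000L,
      burn_in = 5000L,
      rhat_bound = 1.01
    )
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unspecified fields fall back to [default_config()] values.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A full configuration list.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  modify_defaults(default_config(), user)
}

# recursive list merge: values in `user` override `base`
modify_defaults <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_defaults(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

# md5 of the resolved config, recorded in run logs
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = 12)
  unname(tools::md5sum(tf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
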