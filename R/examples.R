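# Built-in example objects: a small water-kefir-like taxonomy, reference
# database, community and classifier profiles used by the documentation,
# tests and the demo pipeline.

#' Example water-kefir taxonomy
#'
#' A compact rooted taxonomy covering the genera typical of water kefir
#' (lactobacilli, \emph{Oenococcus}, \emph{Bifidobacterium},
#' \emph{Pediococcus}, \emph{Leuconostoc}, and the yeasts
#' \emph{Saccharomyces} and \emph{Dekkera}), including a species group, a
#' subspecies and an unranked clade so all rank behaviours are exercised.
#'
#' @return A `taxonomy` object.
#' @export
example_taxonomy <- function() {
  n <- function(id, parent, rank, name) data.frame(
    taxon_id = id, parent_id = parent, rank = rank, name = name,
    stringsAsFactors = FALSE)
  load_taxonomy(rbind(
    n("root", "root", "root", "root"),
    n("d_bacteria", "root", "domain", "Bacteria"),
    n("d_eukaryota", "root", "domain", "Eukaryota"),
    n("p_firmicutes", "d_bacteria", "phylum", "Firmicutes"),
    n("p_actinobacteria", "d_bacteria", "phylum", "Actinobacteria"),
    n("p_ascomycota", "d_eukaryota", "phylum", "Ascomycota"),
    n("c_bacilli", "p_firmicutes", "class", "Bacilli"),
    n("c_actinomycetia", "p_actinobacteria", "class", "Actinomycetia"),
    n("c_saccharomycetes", "p_ascomycota", "class", "Saccharomycetes"),
    n("o_lactobacillales", "c_bacilli", "order", "Lactobacillales"),
    n("o_bifidobacteriales", "c_actinomycetia", "order", "Bifidobacteriales"),
    n("o_saccharomycetales", "c_saccharomycetes", "order",
      "Saccharomycetales"),
    n("f_lactobacillaceae", "o_lactobacillales", "family",
      "Lactobacillaceae"),
    n("f_leuconostocaceae", "o_lactobacillales", "family",
      "Leuconostocaceae"),
    n("f_bifidobacteriaceae", "o_bifidobacteriales", "family",
      "Bifidobacteriaceae"),
    n("f_saccharomycetaceae", "o_saccharomycetales", "family",
      "Saccharomycetaceae"),
    n("f_pichiaceae", "o_saccharomycetales", "family", "Pichiaceae"),
    n("nr_lactobacillus_clade", "f_lactobacillaceae", "no_rank",
      "Lactobacillus clade"),
    n("g_lactobacillus", "nr_lactobacillus_clade", "genus", "Lactobacillus"),
    n("g_pediococcus", "f_lactobacillaceae", "genus", "Pediococcus"),
    n("g_oenococcus", "f_leuconostocaceae", "genus", "Oenococcus"),
    n("g_leuconostoc", "f_leuconostocaceae", "genus", "Leuconostoc"),
    n("g_bifidobacterium", "f_bifidobacteriaceae", "genus",
      "Bifidobacterium"),
    n("g_saccharomyces", "f_saccharomycetaceae", "genus", "Saccharomyces"),
    n("g_dekkera", "f_pichiaceae", "genus", "Dekkera"),
    n("s_l_hilgardii", "g_lactobacillus", "species",
      "Lactobacillus hilgardii"),
    n("s_l_nagelii", "g_lactobacillus", "species", "Lactobacillus nagelii"),
    n("s_l_harbinensis", "g_lactobacillus", "species",
      "Lactobacillus harbinensis"),
    n("sg_l_casei", "g_lactobacillus", "species_group",
      "Lactobacillus casei group"),
    n("s_l_paracasei", "sg_l_casei", "species", "Lactobacillus paracasei"),
    n("ss_l_paracasei_paracasei", "s_l_paracasei", "subspecies",
      "Lactobacillus paracasei subsp. paracasei"),
    n("s_p_damnosus", "g_pediococcus", "species", "Pediococcus damnosus"),
    n("s_o_oeni", "g_oenococcus", "species", "Oenococcus oeni"),
    n("s_o_kitaharae", "g_oenococcus", "species", "Oenococcus kitaharae"),
    n("s_o_alcoholitolerans", "g_oenococcus", "species",
      "Oenococcus alcoholitolerans"),
    n("s_leuc_mesenteroides", "g_leuconostoc", "species",
      "Leuconostoc mesenteroides"),
    n("s_b_aquikefiri", "g_bifidobacterium", "species",
      "Bifidobacterium aquikefiri"),
    n("s_s_cerevisiae", "g_saccharomyces", "species",
      "Saccharomyces cerevisiae"),
    n("s_s_pastorianus", "g_saccharomyces", "species",
      "Saccharomyces pastorianus"),
    n("s_d_bruxellensis", "g_dekkera", "species", "Dekkera bruxellensis")))
}

#' Example reference genome database
#'
#' Reference genomes for the example community, including the three known
#' \emph{Oenococcus} species (so a planted novel relative recruits against
#' several same-genus genomes, and same-genus decoy hits exist). Genome
#' lengths are scaled down (hundreds of kbp instead of Mbp) to keep
#' simulations fast; recruitment breadth depends only on windows per genome,
#' not absolute size.
#'
#' @return A [reference_db()].
#' @export
example_reference_db <- function() {
  reference_db(data.frame(
    genome_id = c("gen_l_hilgardii", "gen_l_nagelii", "gen_b_aquikefiri",
                  "gen_o_oeni", "gen_o_kitaharae", "gen_o_alcoholitolerans",
                  "gen_s_cerevisiae", "gen_d_bruxellensis"),
    species = c("s_l_hilgardii", "s_l_nagelii", "s_b_aquikefiri",
                "s_o_oeni", "s_o_kitaharae", "s_o_alcoholitolerans",
                "s_s_cerevisiae", "s_d_bruxellensis"),
    genus = c("g_lactobacillus", "g_lactobacillus", "g_bifidobacterium",
              "g_oenococcus", "g_oenococcus", "g_oenococcus",
              "g_saccharomyces", "g_dekkera"),
    length = c(200000, 200000, 200000, 200000, 180000, 190000,
               300000, 200000),
    stringsAsFactors = FALSE))
}

#' Example five-member water-kefir community
#'
#' Four members with near-identical reads (sequenced species) and one
#' planted novel relative: reads simulated from the \emph{Oenococcus}
#' reference at identity Normal(77, 3), the uniform 70–85% band that
#' signals a related species missing from the reference database.
#'
#' @return A [community_profile()].
#' @export
example_community <- function() {
  community_profile(data.frame(
    genome_id = c("gen_l_hilgardii", "gen_b_aquikefiri", "gen_s_cerevisiae",
                  "gen_o_oeni", "gen_d_bruxellensis"),
    species = c("s_l_hilgardii", "s_b_aquikefiri", "s_s_cerevisiae",
                "s_o_oeni", "s_d_bruxellensis"),
    abundance = c(0.25, 0.25, 0.20, 0.12, 0.18),
    identity_mean = c(99, 99, 98.5, 77, 99),
    identity_sd = c(0.5, 0.5, 0.8, 3, 0.5),
    genome_length = c(200000, 200000, 300000, 200000, 200000),
    stringsAsFactors = FALSE))
}

#' Example classifier profiles
#'
#' Five synthetic classifiers in the usual priority order. Assignment rates
#' fall with priority (the protein-alignment classifier assigns fewest
#' reads) and the k-mer classifier carries a \emph{Dekkera} blind spot,
#' emulating a database that lacks that genus.
#'
#' @return Named list of [tool_profile()]s in priority order.
#' @export
example_tool_profiles <- function() {
  ps <- list(
    tool_profile("kaiju", 0.55),
    tool_profile("kraken", 0.50, blind_spot = "g_dekkera"),
    tool_profile("blastn_nt", 0.45, misassignment_rate = 0.01),
    tool_profile("blastn_refseq", 0.40),
    tool_profile("blastx_nr", 0.30))
  stats::setNames(ps, vapply(ps, `[[`, character(1), "tool"))
}

#' Illustrative pathway definitions
#'
#' A small set of biosynthesis pathways (amino acids and a vitamin) with
#' plausible gene symbols. Illustrative only — real analyses supply their
#' own curated definitions.
#'
#' @return data.frame `pathway`, `gene`.
#' @export
example_pathways <- function() {
  path <- system.file("extdata", "pathways_example.tsv", package = "kefirmg")
  read_pathway_definitions(path)
}
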