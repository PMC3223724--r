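# locweaver

Genome-wide prediction of protein subcellular localization for
gram-negative (diderm) bacteria.

## The problem

Knowing whether a bacterial protein resides in the cytoplasm, the inner
membrane, the periplasm, the outer membrane, the cell surface or outside the
cell is one of the most informative annotations a genome project can attach
to a gene. No single computational predictor gets this right: the popular
tools only model the common Sec/LepB export route, they miss lipoproteins
exported by the twin-arginine (Tat) pathway, they routinely count signal
peptides as transmembrane spans, the enterobacterial "D at +2" lipoprotein
sorting rule fails outside enterobacteria, and bacteriophage structural
proteins and secretion-system components confuse global predictors entirely.
Orthologous proteins from closely related strains frequently receive
contradictory predictions, which is usually a symptom of a wrong gene model
rather than real biology.

`locweaver` implements a curation-grade strategy for multi-strain panels:

1. **Inventory the export machinery first.** Packaged registries of the
   domains that identify secretins/ushers (18 domains covering T1SS–T8SS),
   the Sec/Tat/Lol/Bam core components and the signal peptidases are used to
   find secretion-system loci by genome context (`find_secretion_loci`), so
   machinery components get their known localization before any sequence
   heuristic runs. TolC-family hits are only promoted to T1SS when
   membrane-fusion/permease domains (HlyD/PrtD/HlyB/LssB families) co-occur
   in the locus, since TolC alone also serves small-molecule efflux.
2. **Scan for every sorting-signal class.** Rule-based scanners cover the
   twin-arginine motif (Z-X-R-R-X-&phi;-&phi;, &phi; hydrophobic, Z
   hydrophilic), the lipobox `[LVIFMST][ASTVIG][GAS]C` with its invariant
   +1 Cys, the composite Tat-lipoprotein signal that LipoP-style and
   TatP-style tools both miss, a Sec/LepB fallback heuristic
   (positive n-region, &ge;7-residue hydrophobic h-region, Ala-X-Ala
   cleavage), twin-glycine bacteriocin leaders, the &beta;-barrel C-terminal
   signature (terminal Phe/Tyr with hydrophobic residues at positions 5, 7
   and 9 from the C-terminus), a trainable C-terminal PSSM
   (`derive_cterm_pssm`), and Kyte–Doolittle hydropathy spans.
3. **Integrate with a decision tree** (`decide`): phage context &rarr;
   machinery registry &rarr; lipoprotein sorting &rarr; Tat &rarr;
   transmembrane spans (discounting a signal peptide miscounted as an
   N-terminal span) &rarr; Sec &rarr; exported branch (&beta;-barrel evidence
   beats a majority vote restricted to periplasm/outer-membrane/
   extracellular) &rarr; location-informative domains and a global majority
   vote. Every call carries an ordered, replayable evidence trail and a
   confidence grade. Domains that occur only in proteins called to one
   compartment are inferred (`infer_domain_locations`) and fed back in a
   second pass that is a fixed point of further iteration.
4. **Reconcile across genomes** (`classify_groups`, `flag_anomalies`):
   ortholog groups with mixed calls, length outliers or members missing a
   signal the rest of the group carries flag probable gene-model errors.
5. **Validate N-termini from proteomics** (`validate_proteome`): partially
   tryptic peptides that map most closely to the N-terminus are explained as
   N-terminal Met excision (Met before Pro or a small residue) or as an
   exact match to a predicted signal-cleavage site.

A deterministic synthetic-data generator (`synth_bundle`) plants every
signal class, locus type, decoy and digest the pipeline handles, with full
ground truth, and is the basis of the package's end-to-end tests.

## Worked example

```r
library(locweaver)

bundle <- synth_bundle(synth_config(seed = 7))     # 19 genomes x 50 proteins
res <- predict_localization(bundle$proteins, bundle$genes,
                            bundle$domain_hits, bundle$tools,
                            bundle$orthologs)
print(res)
```

```
locweaver result: 950 proteins

         CYT        EXTRA           IM      LIPO_IM      LIPO_OM LIPO_SURFACE
         399           57          152           19           57           19
          OM         PERI        PHAGE
          76           95           76
76 secretion loci; 98 substrate candidates

consistent
        51
```

Every protein gets exactly one controlled-vocabulary label; the 76 loci are
the planted fimbrial-usher (T7SS), TolC-dependent T1SS, bacteriocin T1SS and
curli (T8SS) systems, four per genome. A single call shows its audit trail —
here a surface lipoprotein, sorted by lipobox plus Gly/Ser enrichment because
the enterobacterial +2 rule is not trusted in genus mode:

```r
decide(res$records[["S01_0036"]])
#> <S01_0036 -> LIPO_SURFACE (high) trail: phage=no; secretion_component=no;
#>   lipoprotein=LIPO_SURFACE>
```

The inferred location-informative domain map drives the refinement pass:

```r
head(res$domain_map, 3)
#>   accession location n_proteins purity
#> 1 pfam00529  LIPO_IM         19      1
#> 2 pfam00577       OM         19      1
#> 3  pfam0341       IM         19      1
```

A thin CLI wraps the same functions:

```sh
locweaver synth   --seed 3 --outdir fixtures/
locweaver predict --proteome fixtures/SYN01.faa --genome-id SYN01 \
                  --genes fixtures/genes.tsv --domains fixtures/domain_hits.tsv \
                  --tools fixtures/tool_predictions.tsv --out calls.tsv
locweaver orthocheck --calls calls.tsv --orthologs fixtures/orthologs.tsv --out verdicts.tsv
locweaver report  --calls calls.tsv --verdicts verdicts.tsv --out report.txt
```

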