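# acvconf

Conformational analysis of acyclic nucleoside analogues in R.

Acyclovir-like molecules replace the deoxyribose of a natural nucleoside
with a flexible 2-hydroxyethoxymethyl chain, so their shape is described by
five exocyclic torsions and a handful of pseudo-bond observables rather
than by a sugar pucker:

* **phi1** (C4-N9-C1'-O2') — the glycosidic-like base orientation;
  phi1 < 0 is *anti* (class A), phi1 > 0 is *syn* (class B)
* **phi2-phi5** — the chain folds and the hydroxyl orientation
* **R, beta, Phi** — the N9···O5' pseudo-bond distance and the
  C4-N9···O5' / C1'-N9···O5' angles placing the hydroxyl end relative
  to the base plane

Given tabulated relative energies `E_i` (quantum-chemical `dE = ΔE+ZPE` or
`dG`, consumed as inputs and never computed here), species abundances
follow the Boltzmann distribution

```
p_i = exp(-E_i / RT) / Σ_j exp(-E_j / RT),   R = 1.98720425e-3 kcal/(mol·K)
```

The package provides, for structural-chemistry and medicinal-chemistry
users who want the desk-scale part of a conformational study to be
reproducible:

* labeled molecular structures with XYZ (and minimal PDB) I/O, topology
  validation and a Z-matrix (NeRF) builder;
* descriptor computation (`descriptor_set()`), exact torsion driving
  (`set_torsion()`), purine-ring nonplanarity (`base_nonplanarity()`);
* table analytics: syn/anti classification, circular torsion binning,
  Boltzmann populations, energy-band statistics;
* hydrogen-bond detection and typing (intramolecular motifs
  H5'···N3 / H5'···O2' and intermolecular networks of posed multimers);
* a five-torsion grid conformational search (60° steps, 6^5 = 7776 starts)
  with coordinate-descent relaxation under a pluggable energy model,
  circular deduplication and A#/B# ranking;
* a synthetic-data module: idealized tautomer templates (N1, N3, N7,
  OHC, OHT), posed H-bond assemblies, seeded surrogate conformer ensembles
  and packaged transcriptions of the reference tautomer/conformer tables.

## Worked example

```r
library(acvconf)

# Tautomer populations from the packaged energy table (dE = ΔE+ZPE column)
t1 <- tautomer_table()
boltzmann_populations(t1, population_config(298.15, "dE"))
#>   name     mu     dE     dG population
#> 1   N1  5.375  0.000  0.000  4.808e+01
#> 2   N3 11.183 25.529 24.811  9.312e-18
#> 3   N7  7.785 17.516 17.689  6.960e-12
#> 4  OHC  2.100  0.145  0.284  3.764e+01
#> 5  OHT  2.105  0.719  0.830  1.429e+01
```

At room temperature the N1 keto tautomer dominates (48.1%), followed by
the cis-enol OHC (37.6%) and trans-enol OHT (14.3%); the N3 and N7 keto
forms are negligible — the quantities a tautomer-equilibrium UV/VIS
experiment would probe.

```r
# Classify and bin the 78-conformer reference table
t2 <- conformer_table_fixture()
table(classify_conformer(t2)$class)
#>  A  B
#> 47 31
bin_torsions(t2, "phi3", default_torsion_bins()$phi3, round_to = 0)
#>        bin   lo  hi total  A  B
#> 1     bin1   58 180    32 22 10
#> 2     bin2 -180 -58    46 25 21
#> 3 unbinned   NA  NA     0  0  0
energy_band_stats(t2, c(0, 3))$ratio_rounded
#> [1] 0.8
```

47 conformers are *anti*, 31 *syn*; phi3 is bimodal (32 positive / 46
negative); below 3 kcal/mol the anti/syn ratio is 0.8 and rises to 1.7 in
the 3.0–8.5 kcal/mol band.

```r
# Build the global-minimum geometry and find its intramolecular H-bond
tmpl <- build_template("N1", c(phi1 = -74.1, phi2 = 144.7, phi3 = -93.4,
                               phi4 = 71.1, phi5 = -73.3))
descriptor_set(tmpl, name = "A1")
#>   name     R  beta   Phi  phi1  phi2  phi3 phi4  phi5
#> 1   A1 3.683 72.01 53.99 -74.1 144.7 -93.4 71.1 -73.3
detect_hbonds(tmpl)
#>   donor_mol donor hydrogen acceptor_mol acceptor distance_A angle_deg scope
#> 1         0   O5'      H5'            0       N3      1.813     160.8 intra
```

The torsions are realized exactly (R/beta/Phi come from the idealized
template geometry, not from a relaxed structure), and at the
global-minimum torsions the chain folds back so the hydroxyl proton
donates to ring nitrogen N3 — the type (i) motif that stabilizes the
lowest-energy conformers.

```r
# Grid search under the surrogate energy model (reduced 2-torsion demo)
cfg <- search_config(step = 60, torsions = c("phi4", "phi5"))
tab <- deduplicate_and_rank(grid_search(tmpl, toy_energy_model(tmpl), cfg), cfg)
```

## Command line

```sh
Rscript -e 'acvconf::acv_cli()' populations inst/extdata/table1_tautomers.tsv --temperature 298.15
Rscript -e 'acvconf::acv_cli()' simulate --n 100 --seed 7 --out ensemble.tsv
Rscript -e 'acvconf::acv_cli()' report --table1 ... --table2 ... --out report/
```
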