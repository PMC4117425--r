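# flexsite

Structure-based druggability assessment of protein binding pockets with
light protein flexibility, in R.

Rigid-receptor druggability estimators miss *cryptic pockets* — sites that
are too small in the crystal structure but open into drug-like cavities
through side-chain rearrangement and small local backbone movements, as is
common at protein–protein interaction (PPI) interfaces. flexsite detects
candidate pockets on a fine site-point grid, scores them, opens flexible
pockets with a two-stage hydrophobic-probe induced-fit procedure, and
classifies every site as druggable, difficult, cryptic-druggable or not
advanced.

The method in brief:

1. **Pocket detection.** Grid points outside the receptor are *site
   points* when their united-atom carbon probe Lennard-Jones energy is at
   most −1.0 kcal/mol and at least 40 % of 110 cast rays strike the
   receptor surface within 10 Å (the *enclosure* fraction). Supported
   points cluster by single linkage with a 5.0 Å cut; the five largest
   clusters are the candidate sites.
2. **Scoring.** Each site gets enclosure *e*, size *n*, volume *V*,
   hydrophobic *h* and hydrophilic *p* descriptors, and the druggability
   score

   ```
   Dscore  = 0.094·√n + 0.60·e − 0.324·min(p, 1)
   Dscore+ = Dscore + 0.3·h
   ```

3. **Flexibility.** Sites with Dscore+ > 1.3 are opened by induced-fit
   docking of naphthalene, side-chain rotamer repacking, then docking of a
   tetra-substituted naphthalene (TSN, ≈363 Da); the four best models are
   re-detected and re-scored.
4. **Decision.** Druggable when the flexible Dscore+ ≥ 1.7 and the
   flexible volume lies in the drug-like range 160–800 ų;
   *cryptic-druggable* when additionally the rigid pocket was ≤ 100 ų and
   ≤ 96 % enclosed on a chain of ≥ 100 residues. TSN contacts with partner
   chains (≤ 2 Å, hydrogens included) flag PPI-interface pockets.

A generator of synthetic receptor fixtures with analytic ground truth
(spherical and hemispherical cavities, slabs, two-cavity systems, and a
rotamer-gated cryptic cavity) makes every geometric and flexibility stage
testable without any external structure downloads, and a validation
harness reproduces published PPI benchmark error rates and score-variation
statistics from packaged tables.

## Worked example

```r
library(flexsite)

# a synthetic receptor with a gated (cryptic) cavity, written as PDB
fix <- generate_fixture(fixture_spec("gated_cavity"))
write_fixture(fix, "gated.pdb")

records <- run_pipeline("gated.pdb", run_config(seed = 1))
records_table(records)
```

```
  structure_id site_id rigid_dscore_plus rigid_volume rigid_enclosure_pct
1        gated       1               1.8         86.7                84.2
  flex_dscore_plus flex_volume             label rigid_druggable ppi_interface
1              2.1       218.8 cryptic_druggable           FALSE         FALSE
  ligand_pocket
1         FALSE
```

Rigidly, the pocket scores Dscore+ 1.8 but holds only 86.7 ų — far below
drug-like size — with 84 % enclosure. The induced-fit stage swings the
gating lysine side chain out of the cavity, and the re-scored best model
reaches Dscore+ 2.1 at 219 ų: the site is classified `cryptic_druggable`.

On a real structure: `run_pipeline("1abc.pdb", run_config())`, or from the
shell via the thin wrapper

```sh
flexsite run 1abc.pdb --monomer A --seed 1 --out results/
flexsite validate          # reproduce the published benchmark statistics
flexsite fixtures gated_cavity --out gated.pdb --truth truth.json
```

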