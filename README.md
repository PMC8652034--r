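# sse2d — family-wide protein secondary structure 2D diagrams

Secondary structure cartoons drawn from a single protein are hard to compare
across a family: two close homologs can get wildly different diagrams because
classical layout tools only consider local topology. `sse2d` draws 2D
diagrams of protein domains that (i) reflect the **3D arrangement** of the
secondary structure elements (SSEs) — if two elements are close in space,
they are close on the page — and (ii) stay **intercomparable across a
family**, because every member's layout is restrained towards previously
computed members and topologically equivalent elements share a label. A
family-level overlay shows each element with opacity equal to the fraction of
members that carry it.

It is aimed at structural bioinformaticians working with CATH-style domain
families (inputs are PDB/mmCIF files plus chain + residue-range domain
definitions), and at method developers, who can exercise every stage on
synthetic structures with known ground truth.

## Method in brief

1. **Detection** — helices and strands are assigned from Cα geometry alone,
   P-SEA-style: residue *i* is helix-like when d(i,i+2) ∈ [4.8, 6.1] Å and
   d(i,i+3) ∈ [4.35, 5.75] Å, strand-like when d(i,i+2) ∈ [5.8, 7.4] Å
   (windows centred on the canonical trace values 5.43/5.05/6.60 Å), with
   running-median profile smoothing and gap closing for noise robustness.
2. **Cross-annotation** — a consensus reference member is named H1, H2, …/
   E1, E2, … in sequence order; every other member is rigidly superposed
   (Kabsch) and its SSEs aligned to the reference by order-preserving,
   type-constrained dynamic programming on midpoint proximity.
3. **Statistics** — per label: occurrence count, frequency = count/members,
   mean length; labels at frequency ≥ 0.5 are *primary*, the rest
   *secondary*.
4. **Sheets** — strands pair when their mean nearest-Cα distance ≤ 5.5 Å;
   connected components must be simple paths (barrels and bifurcated sheets
   are rejected) and become rigid 2D templates with 4.8-unit spacing.
5. **Layout** — elements (helices, whole sheets) are placed in the plane by
   minimizing the projection stress
   `Σ_{i<j} (‖p_i − p_j‖ − ‖a_i − a_j‖)² + λ Σ_i ‖p_i − s_i‖²`,
   where `a` are 3D anchors (axis midpoints / sheet centroids), `s` a
   previously computed member's layout (λ = 0.05), via deterministic
   gradient descent with backtracking from a principal-plane projection:
   primary elements first, then secondary with primaries frozen, then angle
   assignment from projected 3D axes with a small overlap-reduction sweep.
6. **Rendering** — SVG 1.1; helices as rounded rectangles, strands as N→C
   arrows inside their sheet template, connectors in sequence order; the
   family overlay sets each glyph's `fill-opacity` to its frequency.

## Worked example

```r
library(sse2d)

# a synthetic alpha/beta family: 10 members, 0.3 A coordinate jitter
fam <- makeFamily(familySpec(mixedRecipe(), nMembers = 10,
                             jitterSigma = 0.3, seed = 1))
af  <- annotateStructures(fam$familyId,
                          lapply(fam$members, `[[`, "structure"))
af
#> AnnotatedFamily 9.10.10.10: 10 members, 3-4 SSEs, 4 distinct labels

stats <- computeFamilyStats(af)
head(statsTable(stats), 4)
#>   label count frequency avgLength   type   class
#> 1    E1     7       0.7  5.285714 strand primary
#> 2    E2    10       1.0  5.100000 strand primary
#> 3    H1    10       1.0 11.200000  helix primary
#> 4    H2     9       0.9  9.222222  helix primary

diags <- layoutFamily(af, stats)
diags[[1]]
#> DomainDiagram synA01: 3 elements, stress 0

round(normalizedStress(diags[[2]]), 4)
#> [1] 0.0097

svg <- renderDomainSVG(diags[[1]])                    # one member
fd  <- computeFamilyDiagram(diags, stats)             # family overlay
writeLines(renderFamilySVG(fd), "family_multiple.svg")
```

The frequencies say, e.g., that strand E1 is found in 7 of 10 members (the
other three miss it under the coordinate noise), so in
`family_multiple.svg` its arrow is drawn at 70% opacity. The per-member
normalized stress around 0.01 means 2D inter-element distances reproduce
the 3D anchor distances to about 1%.

Real structures go through the same pipeline via
`readStructure()`/`extractDomain()`, or from the shell:

```sh
Rscript inst/cli/sse2d.R run --ranges ranges.tsv --out outdir --family-id 2.140.10.30
```

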