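# Bowtie2 parameter-optimization scenario: the default setting, the eight
# preset options, and a custom range over three critical parameters
# (seed length -L, extension effort -D, reseeding -R) — 34 combinations.
simulation:
  read_length: 150
  snp_rate: 0.002
  indel_rate: 0.0003
  error_rate: 0.006
mappers:
  - name: bowtie2
    index_command: "bowtie2-build {reference} {reference}"
    map_command: "bowtie2 -x {reference} -U {fastq1} {params} -S {output}"
    parameter_sets:
      - label: default
        args: ""
      - label: very-fast
        args: "--very-fast"
      - label: fast
        args: "--fast"
      - label: sensitive
        args: "--sensitive"
      - label: very-sensitive
        args: "--very-sensitive"
      - label: very-fast-local
        args: "--very-fast-local"
      - label: fast-local
        args: "--fast-local"
      - label: sensitive-local
        args: "--sensitive-local"
      - label: very-sensitive-local
        args: "--very-sensitive-local"
    parameter_grid:
      -L: [18, 20, 22, 25, 28]
      -D: [5, 10, 15, 20, 25]
      -R: [2]
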