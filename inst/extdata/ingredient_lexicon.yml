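# Portuguese ingredient keyword lexicon for the added-nutrient screen.
# Terms are a reconstruction of the documented English keyword glosses
# (the source study published English glosses only); edit freely.
# Single-word terms match whole tokens; multi-word terms match contiguous
# token runs. Plurals are listed explicitly - no stemming is applied.
version: "reconstruction-1.0"
sugar:
  - "açúcar"
  - "açúcares"
  - "mel"
  - "xarope"
  - "xaropes"
  - "melaço"
  - "maltodextrina"
  - "glicose"
  - "glucose"
  - "frutose"
  - "suco concentrado de frutas"
  - "suco concentrado de vegetais"
  - "suco de fruta concentrado"
  - "chocolate"
  - "fondant de leite"
salt:
  - "sal"
  - "cloreto de sódio"
  - "queijo"
  - "queijos"
  - "presunto"
  - "bacon"
  - "salame"
  - "linguiça"
  - "embutidos"
fat:
  - "óleo"
  - "óleos"
  - "azeite"
  - "azeitona"
  - "azeitonas"
  - "manteiga"
  - "creme de leite"
  - "nata"
  - "gordura"
  - "gorduras"
  - "banha"
nns:
  - "aspartame"
  - "sacarina"
  - "sucralose"
  - "ciclamato"
  - "acessulfame"
  - "acessulfame k"
  - "acessulfame de potássio"
  - "estévia"
  - "stevia"
  - "polidextrose"
  - "maltitol"
  - "manitol"
  - "isomaltose"
  - "neotame"
  - "xilitol"
  - "taumatina"
  - "advantame"
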