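# Front-of-package claim pattern lexicon (Portuguese), one pattern set per
# taxonomy cell. The taxonomy has three major categories - health,
# nutrition, environment - with subcategories for health (general health,
# special diets, "natural", others = nutrient-function / disease-risk
# claims) and nutrition (nutrients of concern: saturated fat, trans fat,
# sugar, sodium; nutrients not of concern: fiber, vitamins/minerals,
# unsaturated fats, protein; others: health-related ingredients).
# Patterns match as contiguous token runs after lowercasing and accent
# folding. Hand-coded claim text in the source study is operationalized
# here as this auditable pattern list; patterns are deliberately pairwise
# non-nested across cells.
version: "reconstruction-1.0"
health:
  general:
    - "saudável"
    - "alimento equilibrado"
    - "nutritivo"
    - "faz bem para a saúde"
    - "vida leve"
    - "mantenha a forma"
  special_diets:
    - "sem glúten"
    - "sem lactose"
    - "não contém glúten"
    - "vegano"
    - "vegetariano"
    - "apto para dietas restritivas"
  natural:
    - "100% natural"
    - "natural"
    - "puro"
    - "sem conservantes"
    - "sem aditivos"
    - "sem corantes artificiais"
    - "sem agrotóxicos"
    - "sem hormônios"
  others:
    - "o cálcio ajuda na saúde dos ossos"
    - "ajuda a reduzir o colesterol"
    - "contribui para o funcionamento do intestino"
    - "ajuda nas defesas do organismo"
    - "auxilia na digestão"
nutrition:
  of_concern:
    - "zero açúcar"
    - "sem adição de açúcares"
    - "menos açúcar"
    - "baixo teor de sódio"
    - "reduzido em sódio"
    - "sem gordura trans"
    - "reduzido em gorduras saturadas"
  not_of_concern:
    - "fonte de fibras"
    - "rico em fibras"
    - "fonte de proteína"
    - "rico em proteínas"
    - "rico em vitaminas"
    - "fonte de cálcio"
    - "com ômega 3"
    - "rico em ferro"
  others:
    - "com cereais integrais"
    - "feito com frutas"
    - "com castanhas"
    - "com grãos integrais"
    - "fonte de carboidratos"
environment:
  environment:
    - "orgânico"
    - "orgânica"
    - "produto orgânico certificado"
    - "sem transgênicos"
    - "livre de transgênicos"
    - "amigo da biodiversidade"
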