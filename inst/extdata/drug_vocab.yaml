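# Synonym dictionary for the 12 study antiepileptic drugs.
# Canonical name -> generic spellings, salt forms, and common US brand names.
# This is an editable fixture seeded with widely used brands, not a claim of
# any particular study's exact search strings. Matching is exact (after
# uppercasing, trimming, and trailing dosage/form-token stripping); synonym
# sets must be pairwise disjoint and are validated at load time.
CARBAMAZEPINE:
  - CARBAMAZEPINE
  - TEGRETOL
  - TEGRETOL XR
  - CARBATROL
  - EPITOL
  - EQUETRO
ETHOSUXIMIDE:
  - ETHOSUXIMIDE
  - ZARONTIN
PHENYTOIN:
  - PHENYTOIN
  - PHENYTOIN SODIUM
  - DILANTIN
  - PHENYTEK
  - EPANUTIN
VALPROIC ACID:
  - VALPROIC ACID
  - VALPROATE
  - VALPROATE SODIUM
  - SODIUM VALPROATE
  - DIVALPROEX SODIUM
  - DEPAKOTE
  - DEPAKENE
  - DEPAKINE
  - EPILIM
GABAPENTIN:
  - GABAPENTIN
  - NEURONTIN
  - GRALISE
  - GABAPENTIN ENACARBIL
  - HORIZANT
LAMOTRIGINE:
  - LAMOTRIGINE
  - LAMICTAL
  - LAMICTAL XR
LEVETIRACETAM:
  - LEVETIRACETAM
  - KEPPRA
  - KEPPRA XR
  - SPRITAM
  - ELEPSIA
OXCARBAZEPINE:
  - OXCARBAZEPINE
  - TRILEPTAL
  - OXTELLAR
  - OXTELLAR XR
TOPIRAMATE:
  - TOPIRAMATE
  - TOPAMAX
  - TROKENDI
  - TROKENDI XR
  - QUDEXY
  - QUDEXY XR
ZONISAMIDE:
  - ZONISAMIDE
  - ZONEGRAN
ESLICARBAZEPINE:
  - ESLICARBAZEPINE
  - ESLICARBAZEPINE ACETATE
  - APTIOM
  - ZEBINIX
LACOSAMIDE:
  - LACOSAMIDE
  - VIMPAT
  - MOTPOLY
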