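feature	category	previous_studies
noun_frequency	pos	sig
verb_frequency	pos	sig
noun_ratio	pos	sig
verb_ratio	pos	sig
adjective_ratio	pos	nonsig
pronoun_ratio	pos	sig
adverb_ratio	pos	nonsig
auxiliary_verb_frequency	pos	sig
auxiliary_verb_ratio	pos	sig
conjunction_ratio	pos	sig
noun_to_verb_ratio	pos	nonsig
pronoun_to_noun_ratio	pos	sig
honore_statistic	vocabulary_richness	sig
type_token_ratio	vocabulary_richness	nonsig
brunet_index	vocabulary_richness	nonsig
mean_sentence_length	syntactic	sig
word_count	syntactic	nonsig
sentence_count	syntactic	nonsig
character_count	syntactic	nonsig
total_dependency_distance	syntactic	nonsig
avg_dependency_distance_per_sentence	syntactic	nonsig
dependency_count	syntactic	nonsig
perseveration_mean_dist	perseveration	sig
perseveration_prop_dist_lt_050	perseveration	sig
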