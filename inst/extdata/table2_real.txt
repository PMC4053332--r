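#DIALOGUE DI-B33-1
#TURN A
ed oh god she's still talking isn't she laura never gets off the phone
(S (NP (NNP laura)) (VP (ADVP (RB never)) (VBZ gets) (PP (IN off) (NP (DT the) (NN phone)))))

#TURN B
she doesn't Laura's amazing once on the phone really I've never heard
(S (NP (PRP she)) (VP (VBZ doesn't)))
(S (NP (NNP Laura's)) (ADJP (JJ amazing)))
(VP (ADVP (RB never)) (VBN heard))

#TURN A
you know I had three people try to ring me and constantly engaged here apparently three people
(S (NP (PRP you)) (VP (VBP know)))
(S (NP (PRP I)) (VP (VBD had) (NP (CD three) (NNS people))))

#TURN B
really Laura's amazing when she gets on that phone she just does not get off
(S (NP (NNP Laura's)) (ADJP (JJ amazing)))
(S (NP (PRP she)) (VP (VBZ gets) (PP (IN on) (NP (DT that) (NN phone)))))

#TURN A
I know
(S (NP (PRP I)) (VP (VBP know)))

#TURN B
I've never heard anybody spend so much time on the phone and such useless drivel most of the time
(S (NP (PRP I've)) (VP (ADVP (RB never)) (VBN heard) (NP (NN anybody))))

#TURN A
I feel very sorry for the person talking to her
(S (NP (PRP I)) (VP (VBP feel) (ADJP (RB very) (JJ sorry)) (PP (IN for) (NP (DT the) (NN person)))))

#TURN B
yeah really
(S (INTJ (UH yeah)) (ADVP (RB really)))

#TURN A
it looks a good vehicle yeah
(S (NP (PRP it)) (VP (VBZ looks) (NP (DT a) (JJ good) (NN vehicle))))

#TURN B
it does very handy
(S (NP (PRP it)) (VP (VBZ does) (ADVP (RB very) (JJ handy))))

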