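#DIALOGUE DI-B33-1-chance-other
#TURN A
ed oh god she's still talking isn't she laura never gets off the phone
(S (NP (NNP laura)) (VP (ADVP (RB never)) (VBZ gets) (PP (IN off) (NP (DT the) (NN phone)))))

#TURN V
no but at home what do they speak
(S (NP (PRP they)) (VP (VBP speak)))

#TURN A
you know I had three people try to ring me and constantly engaged here apparently three people
(S (NP (PRP you)) (VP (VBP know)))
(S (NP (PRP I)) (VP (VBD had) (NP (CD three) (NNS people))))

#TURN W
did they look at Forster's work as a whole
(SQ (VBD did) (NP (PRP they)) (VP (VB look) (PP (IN at) (NP (NNP Forster's) (NN work)))))

#TURN A
I know
(S (NP (PRP I)) (VP (VBP know)))

#TURN X
oh yeah I've got a big bag of uh recyclable sort of some time
(S (INTJ (UH oh)) (NP (PRP I've)) (VP (VBN got) (NP (DT a) (JJ big) (NN bag))))

#TURN A
I feel very sorry for the person talking to her
(S (NP (PRP I)) (VP (VBP feel) (ADJP (RB very) (JJ sorry)) (PP (IN for) (NP (DT the) (NN person)))))

#TURN Y
mm
(INTJ (UH mm))

#TURN A
it looks a good vehicle yeah
(S (NP (PRP it)) (VP (VBZ looks) (NP (DT a) (JJ good) (NN vehicle))))

#TURN Z
oh we must try it it was so good grilled
(S (NP (PRP we)) (VP (MD must) (VP (VB try) (NP (PRP it)))))

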