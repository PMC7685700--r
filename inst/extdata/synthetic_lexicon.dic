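%
1	work
2	money
3	death
4	anxiety
5	sadness
6	friends
7	posemo
8	negemo
9	i
%
work*	1
job*	1
deadline*	1
homework	1
internship*	1
resume	1
career*	1
exam*	1
money	2
cash	2
rent	2
loan*	2
salar*	2
budget*	2
tuition	2
invest*	2
pay*	2
death*	3
dead	3
die*	3
dying	3
funeral*	3
grief	3
mortality	3
anxious*	4
anxiety	4
worry	4
worri*	4
nervous*	4
panic*	4
stress*	4
overwhelm*	4
sad*	5	8
cry*	5	8
lonely	5	8
hopeless*	5	8
depress*	5	8
miserable	5	8
friend*	6
buddy	6
buddies	6
roommate*	6
hangout*	6
party	6
parties	6
happy	7
joy*	7
love*	7
great	7
awesome	7
fun	7
relax*	7
hate*	8
angry	8
awful	8
terrible	8
fear*	8
i	9
me	9
my	9
myself	9
mine	9
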