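personal:
- subpsf: Knowledge
  definition: Information about and understanding of the medication process held by the nurse.
  weight: 0.237
- subpsf: Experience
  definition: Work-related knowledge and skill accumulated over years of practice.
  weight: 0.270
- subpsf: Fatigue
  definition: Lack of energy and of the mental drive needed to keep performing the job.
  weight: 0.313
- subpsf: Physical health
  definition: Freedom of the body from disease or abnormal conditions.
  weight: 0.065
- subpsf: Task time (circadian rhythm)
  definition: The time of day at which the task is performed.
  weight: 0.114
job:
- subpsf: Workload
  definition: Relation between a person's mental processing resources and the amount of work demanded.
  weight: 0.385
- subpsf: Availability of work procedures
  definition: Specification of who does what, when, and under which criteria.
  weight: 0.175
- subpsf: Physical environment
  definition: Ambient conditions such as weather, ward environment, nursing station and medication store conditions.
  weight: 0.039
- subpsf: Housekeeping
  definition: Crowding, noise, space constraints, telephones and patient companions around the workplace.
  weight: 0.135
- subpsf: Transparency of responsibilities
  definition: How clearly each person's duties are defined for that person.
  weight: 0.110
- subpsf: Time available
  definition: The time frame employees have to perform their task in an abnormal event.
  weight: 0.156
organization:
- subpsf: Patient safety climate
  definition: Shared understanding of which practices and behaviours are rewarded and supported with regard to patient safety.
  weight: 0.225
- subpsf: Safety culture
  definition: Collective beliefs, values, attitudes and behaviour patterns determining the organization's commitment to care quality and safety.
  weight: 0.209
- subpsf: Training
  definition: Systematic development of the knowledge, skills and attitudes needed for a specific task.
  weight: 0.210
- subpsf: Communication between staff
  definition: Transfer of information and understanding from one person to another.
  weight: 0.099
- subpsf: Supervising staff
  definition: Planning, organizing, directing and controlling of work and employee activities.
  weight: 0.120
- subpsf: Error management culture
  definition: Approach that communicates and deals with errors and their consequences after they occur rather than only preventing them.
  weight: 0.136
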